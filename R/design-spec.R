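#' Specify a tricot trial design problem
#'
#' A tricot trial hands each participant a "package" (incomplete block) of
#' three distinct technology options, labelled by position A, B and C. A
#' design specification fixes the option universe, the number of packages and
#' the randomization seed.
#'
#' @param n_options Number of technology options `t` (at least 3).
#' @param n_packages Number of packages/participants `n` (at least 1).
#' @param option_names Character vector of `n_options` distinct, non-empty
#'   labels. Defaults to `"option_01"`, `"option_02"`, ...
#' @param seed Integer seed; the generator is deterministic given the seed.
#'
#' @return An object of class `"design_spec"`.
#' @seealso [generate_design()], [validate_design()]
#' @export
#' @examples
#' design_spec(10, 20, seed = 42)
design_spec <- function(n_options, n_packages,
                        option_names = sprintf("option_%02d", seq_len(n_options)),
                        seed = 1L) {
  if (!is.numeric(n_options) || length(n_options) != 1L || n_options < 3)
    stop("`n_options` must be a single integer >= 3 (blocks have 3 distinct options)")
  if (!is.numeric(n_packages) || length(n_packages) != 1L || n_packages < 1)
    stop("`n_packages` must be a single integer >= 1")
  n_options <- as.integer(n_options)
  n_packages <- as.integer(n_packages)
  option_names <- as.character(option_names)
  if (length(option_names) != n_options)
    stop(sprintf("`option_names` has length %d but `n_options` is %d",
                 length(option_names), n_options))
  if (anyDuplicated(option_names) || any(!nzchar(option_names)))
    stop("`option_names` must be distinct and non-empty")
  structure(
    list(n_options = n_options, n_packages = n_packages,
         option_names = option_names, seed = as.integer(seed)),
    class = "design_spec"
  )
}

#' Construct a tricot trial design from explicit blocks
#'
#' Packages are numbered 1..n consecutively; row `i` of `blocks` holds the
#' options of package `i` in positions A, B, C.
#'
#' @param blocks An n x 3 character matrix (or data.frame) of option labels.
#' @param option_names The option universe; defaults to the sorted set of
#'   labels appearing in `blocks`.
#' @param spec Optional `design_spec` the design was generated from.
#'
#' @return An object of class `"tricot_design"` with elements `packages`
#'   (n x 3 character matrix with columns A/B/C) and `option_names`.
#' @export
tricot_design <- function(blocks, option_names = NULL, spec = NULL) {
  blocks <- as.matrix(blocks)
  if (ncol(blocks) != 3L) stop("each package must have exactly 3 options")
  mode(blocks) <- "character"
  if (is.null(option_names)) option_names <- sort(unique(as.vector(blocks)))
  unknown <- setdiff(as.vector(blocks), option_names)
  if (length(unknown))
    stop("blocks contain options outside the universe: ",
         paste(unknown, collapse = ", "))
  dup <- which(apply(blocks, 1L, anyDuplicated) > 0L)
  if (length(dup))
    stop("option repeated within package(s): ", paste(dup, collapse = ", "))
  dimnames(blocks) <- list(NULL, c("A", "B", "C"))
  structure(
    list(packages = blocks, option_names = as.character(option_names),
         spec = spec),
    class = "tricot_design"
  )
}

#' @export
print.tricot_design <- function(x, ...) {
  cat(sprintf("tricot design: %d packages, %d options\n",
              nrow(x$packages), length(x$option_names)))
  n_show <- min(6L, nrow(x$packages))
  df <- data.frame(package_id = seq_len(n_show),
                   x$packages[seq_len(n_show), , drop = FALSE])
  print(df, row.names = FALSE)
  if (nrow(x$packages) > n_show)
    cat(sprintf("... and %d more packages\n", nrow(x$packages) - n_show))
  invisible(x)
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("design spec: t = %d options, n = %d packages, seed = %d\n",
              x$n_options, x$n_packages, x$seed))
  invisible(x)
}

# integer matrix of option indices (n x 3) for internal arithmetic
design_index_matrix <- function(design) {
  m <- match(design$packages, design$option_names)
  dim(m) <- dim(design$packages)
  m
}
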