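#' Perturbation-response dataset
#'
#' Pairs an observed steady-state response matrix \code{X} (log2 ratios of
#' perturbed over unperturbed measurements; nodes x conditions) with the
#' matrix \code{U} of external-force values applied in each condition, plus
#' per-node roles. \code{U} is nonzero only on perturbed nodes; an
#' unperturbed reference condition, if present, has an all-zero column in
#' both matrices.
#'
#' @param X N x M numeric response matrix (rows = nodes).
#' @param U N x M numeric perturbation matrix, aligned with \code{X}.
#' @param roles per-node roles (\code{protein}/\code{phenotype}/\code{activity}).
#' @param nodes node names (default: rownames of \code{X}).
#' @param conditions condition labels (default: colnames of \code{X}).
#' @param clamp_mask optional N x M logical matrix of nodes held fixed
#'   (genetic-alteration-style perturbations).
#' @return object of class \code{"perturbation_data"}.
#' @export
perturbation_data <- function(X, U, roles = NULL, nodes = NULL,
                              conditions = NULL, clamp_mask = NULL) {
  X <- as.matrix(X); U <- as.matrix(U)
  if (!all(dim(X) == dim(U))) stop("X and U must have identical dimensions")
  if (any(!is.finite(X))) stop("X contains non-finite entries")
  if (any(!is.finite(U))) stop("U contains non-finite entries")
  n <- nrow(X); m <- ncol(X)
  if (is.null(nodes)) nodes <- rownames(X)
  if (is.null(nodes)) nodes <- paste0("n", seq_len(n))
  if (anyDuplicated(nodes)) stop("duplicate node names: ",
                                 paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  if (is.null(conditions)) conditions <- colnames(X)
  if (is.null(conditions))
    conditions <- if (m > 0) paste0("c", seq_len(m)) else character(0)
  if (!is.null(colnames(U)) && !is.null(conditions) &&
      !identical(colnames(U), as.character(conditions))) {
    bad <- which(colnames(U) != conditions)[1]
    stop(sprintf("condition labels of U and X disagree (first mismatch: column %d, '%s' vs '%s')",
                 bad, colnames(U)[bad], conditions[bad]))
  }
  if (is.null(roles)) roles <- rep("protein", n)
  roles <- match.arg(as.character(roles), c("protein", "phenotype", "activity"),
                     several.ok = TRUE)
  if (length(roles) == 1L) roles <- rep(roles, n)
  if (length(roles) != n) stop("length(roles) must match nrow(X)")
  if (!is.null(clamp_mask)) {
    clamp_mask <- as.matrix(clamp_mask)
    if (!all(dim(clamp_mask) == dim(X))) stop("clamp_mask dimension mismatch")
    storage.mode(clamp_mask) <- "logical"
  }
  dimnames(X) <- dimnames(U) <- list(nodes, conditions)
  structure(list(X = X, U = U, nodes = nodes, roles = roles,
                 conditions = conditions, clamp = clamp_mask),
            class = "perturbation_data")
}

#' @export
print.perturbation_data <- function(x, ...) {
  cat(sprintf("Perturbation dataset: %d nodes x %d conditions\n",
              nrow(x$X), ncol(x$X)))
  tab <- table(factor(x$roles, c("protein", "phenotype", "activity")))
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  perturbed entries in U: %d\n", sum(x$U != 0)))
  excl <- attr(x, "excluded")
  if (length(excl)) cat("  excluded (oscillatory):",
                        paste(excl, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.perturbation_data <- function(x) dim(x$X)

#' Apply measurement noise to simulated responses
#'
#' Applies Gaussian noise with zero mean and standard deviation \code{cv}
#' per entry. The default is multiplicative, \eqn{x \to x (1 + g)},
#' \eqn{g \sim N(0, \gamma)}, so that \eqn{\gamma} is the coefficient of
#' variation of the measurement; an additive mode is available.
#'
#' @param x numeric matrix or [perturbation_data()].
#' @param cv noise level \eqn{\gamma} (e.g. 0.15 for a realistic assay,
#'   0.30 as a worst case); 0 returns the input unchanged.
#' @param seed optional RNG seed.
#' @param mode \code{"multiplicative"} or \code{"additive"}.
#' @return same type as \code{x}.
#' @export
add_noise <- function(x, cv = 0.15, seed = NULL,
                      mode = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  stopifnot(cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(x, "perturbation_data")) {
    x$X <- add_noise(x$X, cv = cv, mode = mode)
    return(x)
  }
  if (cv == 0) return(x)
  g <- matrix(stats::rnorm(length(x), 0, cv), nrow(x), ncol(x))
  if (mode == "multiplicative") x * (1 + g) else x + g
}
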