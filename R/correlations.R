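# Mixed-type correlations for the latent-Gaussian measurement model:
# polychoric (ordinal x ordinal, tetrachoric as its 2x2 special case),
# polyserial (ordinal x continuous) and Pearson (continuous x continuous).
# Estimation is two-step: thresholds from the marginal cumulative
# proportions, then a bounded 1-D likelihood maximisation for rho.

RHO_BOUND <- 0.999

ordinal_thresholds <- function(x) {
  tab <- table(factor(x))
  cum <- cumsum(tab) / sum(tab)
  qnorm(cum[-length(cum)])
}

# cell probabilities of the bivariate-normal contingency table
polychoric_cellprobs <- function(rho, tx, ty) {
  gx <- c(-Inf, tx, Inf)
  gy <- c(-Inf, ty, Inf)
  G <- matrix(pbvnorm(rep(gx, times = length(gy)),
                      rep(gy, each = length(gx)), rho),
              nrow = length(gx))
  P <- G[-1, -1, drop = FALSE] - G[-nrow(G), -1, drop = FALSE] -
    G[-1, -ncol(G), drop = FALSE] + G[-nrow(G), -ncol(G), drop = FALSE]
  pmax(P, 1e-12)
}

#' Polychoric (and tetrachoric) correlation
#'
#' Two-step estimator of the latent bivariate-normal correlation between two
#' ordinal variables: thresholds are the inverse-normal CDF of the marginal
#' cumulative proportions; rho maximises the contingency-table likelihood by
#' bounded one-dimensional optimisation on (-0.999, 0.999) (tolerance 1e-6).
#' A binary variable is simply a 2-category ordinal, so the 2x2 case is the
#' tetrachoric correlation.
#'
#' @param x,y Ordinal vectors (integer codes; any strictly ordered coding).
#' @return An object of class `polychoric_fit`: list with `rho`,
#'   `thresholds_x`, `thresholds_y`, `loglik`, `n`, and `at_bound` (TRUE
#'   when the optimum sits at the rho bound, e.g. degenerate tables).
#' @examples
#' set.seed(1)
#' z <- rnorm(500)
#' x <- findInterval(z + rnorm(500), c(-1, 0, 1))
#' y <- findInterval(z + rnorm(500), c(-1, 0, 1))
#' polychoric(x, y)$rho
#' @export
polychoric <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 10) abort("Need at least 10 complete observations.")
  if (length(unique(x)) < 2) abort("`x` has a single observed category.")
  if (length(unique(y)) < 2) abort("`y` has a single observed category.")

  tx <- ordinal_thresholds(x)
  ty <- ordinal_thresholds(y)
  counts <- table(factor(x), factor(y))

  negll <- function(rho) -sum(counts * log(polychoric_cellprobs(rho, tx, ty)))
  opt <- optimize(negll, c(-RHO_BOUND, RHO_BOUND), tol = 1e-6)
  structure(
    list(rho = opt$minimum, thresholds_x = unname(tx),
         thresholds_y = unname(ty), loglik = -opt$objective, n = n,
         at_bound = abs(opt$minimum) > RHO_BOUND - 1e-3),
    class = "polychoric_fit"
  )
}

#' @export
print.polychoric_fit <- function(x, ...) {
  cat("Polychoric fit: rho =", format(x$rho, digits = 4),
      " (n =", x$n, ")\n")
  invisible(x)
}

#' Polyserial correlation
#'
#' Two-step estimator for an ordinal variable against a continuous one:
#' ordinal thresholds from the margins, the continuous variable standardised,
#' and rho maximising the conditional likelihood
#' `P(x = k | z) = Phi((tau_k - rho z)/sqrt(1-rho^2)) - ...`.
#'
#' @param x Ordinal vector.
#' @param y Continuous vector (non-zero variance).
#' @return The correlation estimate (numeric scalar).
#' @export
polyserial <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 2) abort("`x` has a single observed category.")
  if (sd(y) == 0) abort("`y` has zero variance.")
  tau <- c(-Inf, ordinal_thresholds(x), Inf)
  z <- (y - mean(y)) / sd(y)
  ki <- as.integer(factor(x))
  negll <- function(rho) {
    s <- sqrt(1 - rho^2)
    up <- pnorm((tau[ki + 1L] - rho * z) / s)
    lo <- pnorm((tau[ki] - rho * z) / s)
    -sum(log(pmax(up - lo, 1e-12)))
  }
  optimize(negll, c(-RHO_BOUND, RHO_BOUND), tol = 1e-6)$minimum
}

#' Mixed-type correlation matrix
#'
#' Pairwise dispatch over the variable types: ordinal/ordinal (and any pair
#' involving a binary variable, treated as 2-category ordinal) uses
#' [polychoric()]; ordinal/continuous uses [polyserial()];
#' continuous/continuous uses Pearson. The pairwise matrix need not be
#' jointly positive semi-definite, so it is passed through [nearest_psd()].
#'
#' @param data A data frame / cohort tibble.
#' @param types Named character vector of types; taken from cohort
#'   attributes or inferred when `NULL`.
#' @param columns Variables to include (default: all typed columns).
#' @param rank_transform If `TRUE`, continuous columns are replaced by
#'   normal scores (a nonparanormal-style pre-transform) before Pearson /
#'   polyserial estimation.
#' @return An object of class `correlation_matrix`: list with `values`
#'   (p x p matrix), `method_map` (tibble of pairwise estimators), `n`,
#'   and `repaired` (TRUE if the PSD repair changed the matrix).
#' @export
mixed_cor <- function(data, types = NULL, columns = NULL,
                      rank_transform = FALSE) {
  types <- types %||% cohort_types(data) %||% infer_types(data)
  columns <- columns %||% names(types)
  missing_t <- setdiff(columns, names(types))
  if (length(missing_t)) {
    abort(paste0("No type for column(s): ", paste(missing_t, collapse = ", ")))
  }
  types <- types[columns]
  comms <- cohort_communities(data)
  data <- data[stats::complete.cases(data[columns]), columns, drop = FALSE]
  n <- nrow(data)
  p <- length(columns)
  if (rank_transform) {
    for (cl in columns[types == "continuous"]) {
      r <- rank(data[[cl]])
      data[[cl]] <- qnorm(r / (n + 1))
    }
  }

  eff <- ifelse(types == "continuous", "continuous", "ordinal")
  # Pearson entries come from one cor() call; only pairs involving an
  # ordinal/binary variable need a likelihood-based estimate.
  R <- cor(as.matrix(data))
  dimnames(R) <- list(columns, columns)
  errors <- character(0)
  iu <- which(upper.tri(R), arr.ind = TRUE)
  methods <- character(nrow(iu))
  for (k in seq_len(nrow(iu))) {
    i <- iu[k, 1]; j <- iu[k, 2]
    xi <- data[[i]]; xj <- data[[j]]
    meth <- if (eff[i] == "ordinal" && eff[j] == "ordinal") {
      if (length(unique(xi)) == 2 && length(unique(xj)) == 2)
        "tetrachoric" else "polychoric"
    } else if (eff[i] == "continuous" && eff[j] == "continuous") {
      "pearson"
    } else "polyserial"
    methods[k] <- meth
    if (meth == "pearson") next
    r <- tryCatch(
      if (meth == "polyserial") {
        if (eff[i] == "ordinal") polyserial(xi, xj) else polyserial(xj, xi)
      } else polychoric(xi, xj)$rho,
      error = function(e) {
        errors <<- c(errors, paste0(columns[i], "/", columns[j], ": ",
                                    conditionMessage(e)))
        NA_real_
      }
    )
    R[i, j] <- R[j, i] <- r
  }
  pairs_i <- columns[iu[, 1]]; pairs_j <- columns[iu[, 2]]
  if (length(errors)) {
    abort(paste0("Correlation estimation failed for ", length(errors),
                 " pair(s):\n", paste(errors, collapse = "\n")))
  }
  repaired_out <- nearest_psd(R)
  structure(
    list(values = repaired_out$values,
         method_map = tibble::tibble(var1 = pairs_i, var2 = pairs_j,
                                     method = methods),
         n = n, types = types, repaired = repaired_out$repaired,
         communities = comms),
    class = "correlation_matrix"
  )
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("Mixed-type correlation matrix: ", ncol(x$values), " variables, n = ",
      x$n, if (x$repaired) " (PSD-repaired)", "\n", sep = "")
  invisible(x)
}

#' Nearest positive semi-definite correlation matrix
#'
#' Clips eigenvalues at `floor`, reconstructs, and rescales to unit
#' diagonal. Idempotent on matrices that are already PSD.
#'
#' @param M Symmetric matrix with unit diagonal.
#' @param floor Eigenvalue floor (default 1e-6).
#' @return List with `values` (repaired matrix) and `repaired` flag.
#' @export
nearest_psd <- function(M, floor = 1e-6) {
  stopifnot(isSymmetric(unname(M), tol = 1e-8))
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) >= floor) {
    return(list(values = M, repaired = FALSE))
  }
  R <- M
  # rescaling to unit diagonal can push an eigenvalue back under the
  # floor, so clip-and-rescale is iterated to a fixed point
  for (i in 1:20) {
    e <- eigen(R, symmetric = TRUE)
    if (min(e$values) >= floor * 0.99) break
    ev <- pmax(e$values, floor)
    R <- e$vectors %*% (ev * t(e$vectors))
    d <- sqrt(diag(R))
    R <- R / outer(d, d)
    diag(R) <- 1
    R <- (R + t(R)) / 2
  }
  dimnames(R) <- dimnames(M)
  list(values = R, repaired = TRUE)
}
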