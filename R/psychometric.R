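#' Lapse-augmented logistic psychometric fit
#'
#' Maximum-likelihood fit of choices as a function of signed objective
#' evidence strength (expected logLR, negative for left sources):
#' \deqn{P(R) = \lambda + \frac{1 - 2\lambda}{1 + e^{-(\beta_0 + \beta_e E)}}.}
#' In `joint` mode the three parameters are shared across correlation
#' conditions; in `separate` mode each correlation condition gets its own
#' triplet (nine free parameters).
#'
#' @param dataset behavioral data frame; needs `choice`, `source`,
#'   `correlation_condition`, and either a signed evidence column `E` or
#'   the columns (`mu_rho`, `rho`) plus `sigma_g` to compute it.
#' @param mode `"joint"` or `"separate"`.
#' @param sigma_g generative SD used to compute expected logLR when `E` is
#'   absent.
#' @return Object of class `psychometric_fit` with `coefficients` (matrix,
#'   one row per fitted condition set), `log_likelihood`, `n_params`,
#'   `aic`, `mode`, and `separation_flag`.
#' @export
fit_psychometric <- function(dataset, mode = c("joint", "separate"),
                             sigma_g = 0.1) {
  mode <- match.arg(mode)
  stopifnot(all(c("choice", "source") %in% names(dataset)))
  y <- as.integer(dataset$choice == "right")
  if (!is.null(dataset$E)) {
    e <- dataset$E
  } else {
    stopifnot(all(c("mu_rho", "rho") %in% names(dataset)))
    # signed expected logLR: sign carried by mu_rho, magnitude 4mu^2/(s^2(1+rho))
    e <- sign(dataset$mu_rho) * 4 * dataset$mu_rho^2 /
      (sigma_g^2 * (1 + dataset$rho))
  }

  fit_one <- function(yy, ee) {
    nll <- function(par) {
      b0 <- par[1]; be <- par[2]; lam <- par[3]
      p <- lam + (1 - 2 * lam) / (1 + exp(-(b0 + be * ee)))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -sum(ifelse(yy == 1L, log(p), log(1 - p)))
    }
    opt <- stats::optim(c(0, 0.5, 0.01), nll, method = "L-BFGS-B",
                        lower = c(-20, -20, 0), upper = c(20, 20, 0.499))
    hit_edge <- any(abs(opt$par[1:2]) > 19.5)
    list(par = stats::setNames(opt$par, c("beta_0", "beta_e", "lapse")),
         logL = -opt$value, separation = hit_edge)
  }

  if (mode == "joint") {
    f <- fit_one(y, e)
    coefs <- matrix(f$par, nrow = 1,
                    dimnames = list("all", names(f$par)))
    ll <- f$logL
    n_par <- 3L
    sep <- f$separation
  } else {
    conds <- sort(unique(dataset$correlation_condition))
    fits <- lapply(conds, function(cc) {
      i <- dataset$correlation_condition == cc
      fit_one(y[i], e[i])
    })
    coefs <- do.call(rbind, lapply(fits, `[[`, "par"))
    rownames(coefs) <- conds
    ll <- sum(vapply(fits, `[[`, numeric(1), "logL"))
    n_par <- 3L * length(conds)
    sep <- any(vapply(fits, `[[`, logical(1), "separation"))
  }
  if (sep) warning("possible complete separation; slope at its bound")
  structure(list(coefficients = coefs, log_likelihood = ll,
                 n_params = n_par, aic = aic(ll, n_par), mode = mode,
                 separation_flag = sep),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("Psychometric fit (%s): logL = %.2f, AIC = %.2f\n",
              x$mode, x$log_likelihood, x$aic))
  print(round(x$coefficients, 4))
  invisible(x)
}
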