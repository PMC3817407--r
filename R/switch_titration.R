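# Mechanistic sigma/anti-sigma sequestration model for threshold-gated
# switches: 1:1 equilibrium binding (molecular titration), a saturating
# promoter response to free sigma, and phenomenological Hill fits of the
# resulting transfer functions.

#' Parameters of the sigma/anti-sigma titration switch
#'
#' @param sigma_per_input conversion slope: total sigma produced per unit
#'   of input promoter activity.
#' @param anti_total total anti-sigma concentration (arbitrary
#'   concentration units, the same units as sigma and `kd`).
#' @param kd sigma:anti-sigma dissociation constant (> 0).
#' @param vmax fluorescence at promoter saturation.
#' @param k_half free-sigma concentration at half-maximal promoter
#'   output (> 0).
#' @param basal0 reporter fluorescence at zero free sigma.
#' @return object of class `ecf_titration_params`.
#' @export
titration_params <- function(sigma_per_input = 1, anti_total = 0, kd = 0.01,
                             vmax = 1000, k_half = 0.5, basal0 = 2) {
  vals <- c(sigma_per_input = sigma_per_input, anti_total = anti_total,
            kd = kd, vmax = vmax, k_half = k_half, basal0 = basal0)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all titration parameters must be finite and nonnegative")
  if (kd <= 0) stop("kd must be positive")
  if (k_half <= 0) stop("k_half must be positive")
  structure(as.list(vals), class = "ecf_titration_params")
}

#' Free sigma concentration under 1:1 sequestration
#'
#' Solves the equilibrium mass balance for 1:1 binding of sigma and
#' anti-sigma: the unique nonnegative root of
#' `S^2 + (anti_total + kd - sigma_total) S - kd sigma_total = 0`,
#' computed with the numerically robust quadratic formulation (no
#' cancellation near the sigma_total = anti_total equivalence point).
#' Vectorised over `sigma_total`.
#'
#' @param sigma_total total sigma concentration(s), nonnegative.
#' @param anti_total total anti-sigma concentration, nonnegative.
#' @param kd dissociation constant (> 0).
#' @return free sigma concentration(s).
#' @examples
#' free_sigma(10, 0, 1)          # 10: no sequestrant
#' free_sigma(10, 5, 1e-9)       # ~5: tight-binding limit
#' @export
free_sigma <- function(sigma_total, anti_total, kd) {
  if (!is_number(kd) || kd <= 0) stop("kd must be a positive number")
  if (any(sigma_total < 0) || anti_total < 0)
    stop("concentrations must be nonnegative")
  b <- anti_total + kd - sigma_total
  c0 <- kd * sigma_total
  disc <- sqrt(b^2 + 4 * c0)
  ifelse(b > 0, ifelse(c0 == 0, 0, 2 * c0 / (b + disc)), (disc - b) / 2)
}

#' Simulate a switch transfer function
#'
#' `output(x) = basal0 + vmax * S/(k_half + S)` with
#' `S = free_sigma(sigma_per_input * x, anti_total, kd)`; monotone
#' non-decreasing in the input x.
#'
#' @param params an `ecf_titration_params`.
#' @param inputs nonnegative input activity levels.
#' @return object of class `ecf_transfer`: data.frame with columns
#'   `input`, `output`.
#' @export
simulate_transfer <- function(params, inputs) {
  stopifnot(inherits(params, "ecf_titration_params"))
  if (length(inputs) == 0L || any(inputs < 0))
    stop("inputs must be non-empty and nonnegative")
  s <- free_sigma(params$sigma_per_input * inputs, params$anti_total,
                  params$kd)
  out <- data.frame(input = inputs,
                    output = params$basal0 +
                      params$vmax * s / (params$k_half + s))
  class(out) <- c("ecf_transfer", class(out))
  out
}

#' Fit a Hill function to a transfer function
#'
#' Least squares on log outputs for
#' `y = basal + amplitude * x^n / (k^n + x^n)`, multi-started over
#' initial Hill coefficients `{0.5, 1, 2, 4, 8}` and initial thresholds
#' at three quantiles of the positive inputs, with `n` bounded in
#' `[0.2, 12]`.  Fitting in log space weights the low-output regime
#' where the basal level matters.  Flat data (output range below twice
#' the noise floor, or a dynamic range under 5%) are returned with the
#' `unidentifiable` flag instead of a spurious `n`.
#'
#' @param tf an `ecf_transfer` (or anything with `input`/`output`
#'   columns), or a numeric input vector when `outputs` is given.
#' @param outputs optional numeric outputs matching `tf` as inputs.
#' @param noise_floor known measurement noise scale on the output.
#' @return object of class `ecf_hill_fit`: list with `basal`,
#'   `amplitude`, `k`, `n`, `rss` (residual sum of squares in log
#'   space), `unidentifiable`, `convergence`.
#' @export
fit_hill <- function(tf, outputs = NULL, noise_floor = 0) {
  if (is.null(outputs)) { x <- tf$input; y <- tf$output }
  else { x <- as.numeric(tf); y <- outputs }
  if (length(x) != length(y) || anyNA(x) || anyNA(y))
    stop("inputs and outputs must match and be complete")
  if (length(unique(x)) < 5L) stop("need at least 5 distinct input levels")
  if (any(x < 0) || any(y <= 0)) stop("inputs nonnegative, outputs positive")

  rng <- max(y) - min(y)
  if (max(y) / min(y) < 1.05 || rng < 2 * noise_floor) {
    return(structure(list(basal = exp(mean(log(y))), amplitude = 0,
                          k = NA_real_, n = NA_real_,
                          rss = sum((log(y) - mean(log(y)))^2),
                          unidentifiable = TRUE, convergence = 0L),
                     class = "ecf_hill_fit"))
  }

  xp <- sort(unique(x[x > 0]))
  obj <- function(p) {
    basal <- exp(p[1]); amp <- exp(p[2]); k <- exp(p[3]); n <- p[4]
    yhat <- basal + amp * ifelse(x == 0, 0, x^n / (k^n + x^n))
    sum((log(y) - log(yhat))^2)
  }
  # data-driven half-max guess: input where the output crosses mid-range
  mid <- min(y) + rng / 2
  k0_data <- x[which.min(abs(y - mid))]
  if (!is.finite(k0_data) || k0_data <= 0) k0_data <- stats::median(xp)
  k_starts <- unique(pmax(c(k0_data, stats::quantile(xp, c(0.25, 0.75))),
                          min(xp)))
  lower <- c(log(min(y) * 1e-3), log(rng * 1e-3), log(min(xp) / 100), 0.2)
  upper <- c(log(max(y) * 2), log(rng * 100), log(max(xp) * 100), 12)
  best <- NULL
  for (n0 in c(0.5, 1, 2, 4, 8)) for (k0 in k_starts) {
    p0 <- pmin(pmax(c(log(max(min(y), 1e-12)), log(rng), log(k0), n0),
                    lower), upper)
    fit <- tryCatch(
      optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 10000, factr = 1e3, pgtol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("Hill fit failed from every start")
  structure(list(basal = exp(best$par[1]), amplitude = exp(best$par[2]),
                 k = exp(best$par[3]), n = best$par[4], rss = best$value,
                 unidentifiable = FALSE, convergence = best$convergence),
            class = "ecf_hill_fit")
}

#' @export
print.ecf_hill_fit <- function(x, ...) {
  if (x$unidentifiable)
    cat(sprintf("Hill fit: flat data (basal %.3g), unidentifiable\n", x$basal))
  else
    cat(sprintf("Hill fit: basal %.3g + %.3g * x^%.2f/(%.3g^%.2f + x^%.2f), rss %.3g\n",
                x$basal, x$amplitude, x$n, x$k, x$n, x$n, x$rss))
  invisible(x)
}

#' Tuning curve: switch behaviour across anti-sigma expression levels
#'
#' Simulates and Hill-fits the transfer function at each anti-sigma
#' level, reporting how sequestration lowers the basal (OFF-state)
#' output, raises the apparent cooperativity, and shifts the activation
#' threshold.  The basal column is the simulated output at the lowest
#' input level (the OFF state of the switch; uninduced input promoters
#' leak, so the grid should start at a small positive input), which is
#' pointwise non-increasing in the anti-sigma level; the Hill fit's own
#' basal parameter is reported separately as `hill_basal`.
#'
#' @param params_base an `ecf_titration_params`; its `anti_total` is
#'   overridden by each level.
#' @param anti_levels ascending nonnegative anti-sigma totals.
#' @param inputs input grid passed to [simulate_transfer()]; the lowest
#'   level defines the OFF state.
#' @return data.frame of class `ecf_tuning_curve` with one row per anti
#'   level (`anti_total, basal, hill_basal, amplitude, k, n, rss,
#'   unidentifiable`) and attributes `basal_fold_drop` (max basal / min
#'   basal), `threshold_shift` (max k / min k over identifiable fits).
#' @export
tuning_curve <- function(params_base, anti_levels, inputs) {
  stopifnot(inherits(params_base, "ecf_titration_params"))
  if (is.unsorted(anti_levels)) stop("anti_levels must be sorted ascending")
  rows <- lapply(anti_levels, function(a) {
    p <- params_base; p$anti_total <- a
    tf <- simulate_transfer(p, inputs)
    fit <- fit_hill(tf)
    data.frame(anti_total = a, basal = tf$output[which.min(tf$input)],
               hill_basal = fit$basal, amplitude = fit$amplitude,
               k = fit$k, n = fit$n, rss = fit$rss,
               unidentifiable = fit$unidentifiable)
  })
  out <- do.call(rbind, rows)
  ks <- out$k[!out$unidentifiable]
  attr(out, "basal_fold_drop") <- max(out$basal) / min(out$basal)
  attr(out, "threshold_shift") <- if (length(ks)) max(ks) / min(ks) else NA_real_
  class(out) <- c("ecf_tuning_curve", class(out))
  out
}
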