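#' Fit Michaelis-Menten kinetics by nonlinear least squares
#'
#' Fits `v = kcat * S / (Km + S)` to normalised rates (`v = rate / [E]`,
#' 1/s) by Levenberg-Marquardt least squares (no Lineweaver-Burk
#' linearisation). Start values are `Km0 = median(S)`, `kcat0 = max(v)`;
#' convergence is declared when the relative parameter change falls below
#' 1e-10, with at most 500 iterations.
#'
#' @param substrate_conc Substrate concentrations (M), >= 4 distinct positive
#'   values (replicates at a concentration are allowed).
#' @param rate Observed rates (1/s), same length.
#' @return An object of class `mm_fit`: kinetic parameters `kcat` (1/s),
#'   `Km` (M), `kcat_over_Km` (1/M/s), standard errors where available, and
#'   the underlying `nls` fit.
#' @examples
#' S <- c(1, 3, 8.5, 30, 100) * 1e-6
#' v <- 0.59 * S / (8.5e-6 + S)
#' fit <- mm_fit(S, v)
#' coef(fit)
#' @export
mm_fit <- function(substrate_conc, rate) {
  S <- as.numeric(substrate_conc); v <- as.numeric(rate)
  if (length(S) != length(v)) gtb_shape_error("conc and rate lengths differ")
  if (length(S) < 4) gtb_fit_error("need at least 4 data points")
  if (any(S <= 0)) gtb_fit_error("concentrations must be positive")
  if (length(unique(S)) < 2) gtb_fit_error("concentrations must be distinct")
  dat <- data.frame(S = S, v = v)
  start <- list(kcat = max(v), Km = stats::median(S))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ kcat * S / (Km + S), data = dat, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500, ptol = 1e-10,
                                           ftol = 1e-10)),
    error = function(e) gtb_fit_error(paste0("MM fit failed: ",
                                             conditionMessage(e))))
  est <- stats::coef(fit)
  if (any(est <= 0)) {
    gtb_fit_error(sprintf("non-positive parameter estimate (kcat=%.3g, Km=%.3g)",
                          est["kcat"], est["Km"]))
  }
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(kcat = NA_real_, Km = NA_real_))
  structure(list(kcat = unname(est["kcat"]), Km = unname(est["Km"]),
                 kcat_over_Km = unname(est["kcat"] / est["Km"]),
                 se = se, data = dat, nls = fit),
            class = "mm_fit")
}

#' Construct kinetic parameters without fitting
#'
#' Container for published constants (e.g. for fold-change arithmetic against
#' a reference enzyme).
#'
#' @param kcat Turnover number (1/s).
#' @param Km Michaelis constant (M).
#' @return An `mm_fit`-compatible `kinetic_params` object.
#' @export
kinetic_params <- function(kcat, Km) {
  if (kcat <= 0 || Km <= 0) gtb_argument_error("parameters must be positive")
  structure(list(kcat = kcat, Km = Km, kcat_over_Km = kcat / Km,
                 se = c(kcat = NA_real_, Km = NA_real_)),
            class = c("kinetic_params", "mm_fit"))
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten parameters\n")
  cat(sprintf("  kcat     = %.3g 1/s%s\n", x$kcat,
              if (is.finite(x$se["kcat"])) sprintf(" (se %.2g)", x$se["kcat"]) else ""))
  cat(sprintf("  Km       = %.3g M%s\n", x$Km,
              if (is.finite(x$se["Km"])) sprintf(" (se %.2g)", x$se["Km"]) else ""))
  cat(sprintf("  kcat/Km  = %.3g 1/(M s)\n", x$kcat_over_Km))
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) {
  c(kcat = object$kcat, Km = object$Km)
}

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  S <- if (is.null(newdata)) object$data$S else
    (if (is.data.frame(newdata)) newdata$S else as.numeric(newdata))
  object$kcat * S / (object$Km + S)
}

#' @export
fitted.mm_fit <- function(object, ...) predict(object)

#' @export
residuals.mm_fit <- function(object, ...) object$data$v - fitted(object)

#' @export
summary.mm_fit <- function(object, ...) {
  cat("Michaelis-Menten nonlinear least-squares fit\n")
  print(object)
  if (!is.null(object$nls)) {
    cat(sprintf("  residual sd = %.3g on %d points\n",
                summary(object$nls)$sigma, nrow(object$data)))
  }
  invisible(object)
}

#' @export
plot.mm_fit <- function(x, ...) {
  S <- x$data$S
  grid <- seq(0, max(S) * 1.05, length.out = 200)
  plot(S, x$data$v, xlab = "[S] (M)", ylab = "v (1/s)",
       main = "Michaelis-Menten fit", ...)
  graphics::lines(grid, x$kcat * grid / (x$Km + grid))
  invisible(x)
}

# Round to n significant figures (table-reproduction convention).
signif2 <- function(x) signif(x, 2)

#' Derived kinetic constants and fold changes vs a reference enzyme
#'
#' Computes catalytic efficiency `kcat/Km` (reported to 2 significant figures
#' for table reproduction) and fold changes of `kcat` and `Km` against a
#' reference, expressed as the ratio `>= 1` with a direction flag: `"down"`
#' when the enzyme's value is below the reference, `"up"` otherwise.
#'
#' @param params `mm_fit` or `kinetic_params` for the enzyme of interest.
#' @param reference Same, for the reference (e.g. wild type). Optional.
#' @return A list: `efficiency` (1/M/s), `efficiency_2sf`, and (if a
#'   reference is given) `kcat_fold`, `kcat_direction`, `km_fold`,
#'   `km_direction`, each fold rounded to 2 significant figures.
#' @examples
#' wt <- kinetic_params(kcat = 0.59, Km = 8.5e-6)
#' mut <- kinetic_params(kcat = 0.21, Km = 1.6e-6)
#' derived_constants(mut, wt)
#' @export
derived_constants <- function(params, reference = NULL) {
  eff <- params$kcat / params$Km
  out <- list(efficiency = eff, efficiency_2sf = signif2(eff))
  if (!is.null(reference)) {
    fold <- function(x, ref) {
      r <- max(x / ref, ref / x)
      list(fold = signif2(r), direction = if (x < ref) "down" else "up")
    }
    fk <- fold(params$kcat, reference$kcat)
    fm <- fold(params$Km, reference$Km)
    out$kcat_fold <- fk$fold; out$kcat_direction <- fk$direction
    out$km_fold <- fm$fold;   out$km_direction <- fm$direction
  }
  out
}

#' Read a kinetic dataset from CSV
#'
#' Expected columns: `conc_M`, `rate_per_s`.
#'
#' @param path CSV path.
#' @return data.frame with columns `conc_M`, `rate_per_s`.
#' @export
read_kinetics_csv <- function(path) {
  if (!file.exists(path)) gtb_io_error(paste0("file not found: ", path))
  df <- utils::read.csv(path)
  if (!all(c("conc_M", "rate_per_s") %in% names(df))) {
    gtb_format_error("kinetics CSV needs columns conc_M, rate_per_s")
  }
  df
}

#' Write a kinetics summary table as TSV
#'
#' One row per enzyme, mirroring the usual kinetic-constant table layout:
#' kcat, Km, kcat/Km and fold changes vs the first (reference) row.
#'
#' @param fits Named list of `mm_fit`/`kinetic_params`; the first entry is
#'   the reference.
#' @param path Output path.
#' @return Invisibly, the data.frame written.
#' @export
write_kinetics_tsv <- function(fits, path) {
  ref <- fits[[1]]
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    d <- derived_constants(f, if (i == 1) NULL else ref)
    data.frame(enzyme = names(fits)[i],
               kcat_per_s = f$kcat,
               kcat_fold = if (i == 1) NA else
                 sprintf("%g %s", d$kcat_fold,
                         if (d$kcat_direction == "down") "v" else "^"),
               Km_M = f$Km,
               km_fold = if (i == 1) NA else
                 sprintf("%g %s", d$km_fold,
                         if (d$km_direction == "down") "v" else "^"),
               kcat_over_Km = d$efficiency_2sf)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
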