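#' Convert glucose to starch equivalents
#'
#' Glucose released during enzymatic hydrolysis is converted to anhydrous
#' starch equivalents by the stoichiometric factor 0.9 (162/180, the loss of
#' one water molecule per glycosidic bond).
#'
#' @param glucose Numeric vector of glucose amounts or concentrations
#'   (any consistent unit); must be non-negative.
#' @return Numeric vector of starch equivalents, `0.9 * glucose`.
#' @examples
#' starch_from_glucose(1)    # 0.9
#' starch_from_glucose(100)  # 90
#' @export
starch_from_glucose <- function(glucose) {
  if (any(!is.finite(glucose) | glucose < 0))
    stop("glucose must be finite and non-negative")
  0.9 * glucose
}

#' Build a hydrolysis curve object
#'
#' A hydrolysis curve holds glucose readings taken at increasing incubation
#' times together with the total starch of the sample, which puts the
#' hydrolyzed fraction on a percent basis.
#'
#' @param sample Sample identifier (scalar character).
#' @param times Incubation times in minutes, strictly increasing; a leading
#'   t = 0 point is allowed.
#' @param glucose Glucose readings, one per time point, same percent-of-starch
#'   basis as `total_starch` (i.e. glucose units such that
#'   `glucose * 0.9 / total_starch * 100` is percent starch hydrolyzed).
#' @param total_starch Total starch of the sample (> 0), same unit basis as
#'   `glucose`; default 100 so readings are directly glucose-percent.
#' @return Object of class `hydrolysis_curve`.
#' @export
hydrolysis_curve <- function(sample, times, glucose, total_starch = 100) {
  stopifnot(length(times) == length(glucose))
  if (any(!is.finite(times)) || any(diff(times) <= 0) || any(times < 0))
    stop("times must be non-negative and strictly increasing")
  if (any(!is.finite(glucose) | glucose < 0))
    stop("glucose readings must be finite and non-negative")
  if (!is.finite(total_starch) || total_starch <= 0)
    stop("total_starch must be positive")
  structure(
    list(sample = as.character(sample)[1], times = as.numeric(times),
         glucose = as.numeric(glucose), total_starch = as.numeric(total_starch)),
    class = "hydrolysis_curve")
}

#' @export
print.hydrolysis_curve <- function(x, ...) {
  cat(sprintf("<hydrolysis_curve> %s: %d points over [%g, %g] min\n",
              x$sample, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

# percent starch hydrolyzed at each time point
.curve_pct <- function(curve) {
  starch_from_glucose(curve$glucose) / curve$total_starch * 100
}

#' Fit the first-order hydrolysis model C(t) = Calpha (1 - exp(-k t))
#'
#' Starch digestion follows first-order kinetics toward an equilibrium
#' plateau: `C(t) = Calpha * (1 - exp(-k * t))`, with `C` the percent of total
#' starch hydrolyzed at time `t` (minutes), `Calpha` the equilibrium percent
#' hydrolyzed and `k` the kinetic constant per minute.  The fit is bounded
#' least squares (`Calpha` in \[0, 110\], `k` in (0, 1\]) with multiple `k`
#' starts from `(max(C), 0.01)`, since flat curves can let `k` collapse.
#'
#' `Calpha` is taken as the fitted asymptote.  A plug-in alternative
#' (`calpha = "plugin"`) uses the last observed reading directly, for users
#' who prefer the observed end-point over the asymptote.
#'
#' @param curve A [hydrolysis_curve()] with at least 3 distinct positive time
#'   points.
#' @param calpha Either `"fit"` (default, fitted asymptote) or `"plugin"`
#'   (fix `Calpha` at the final observed percent and fit only `k`).
#' @return Object of class `kinetic_fit` with fields `sample`, `calpha`, `k`,
#'   `converged`, `identifiable`, `rss`, `auc` (over \[0, 180\] min by default
#'   grid convention).
#' @export
fit_first_order <- function(curve, calpha = c("fit", "plugin")) {
  calpha <- match.arg(calpha)
  stopifnot(inherits(curve, "hydrolysis_curve"))
  keep <- curve$times > 0
  tt <- curve$times[keep]
  if (length(unique(tt)) < 3)
    stop("need at least 3 distinct positive time points")
  cc <- .curve_pct(curve)[keep]

  out <- list(sample = curve$sample, calpha = NA_real_, k = NA_real_,
              converged = FALSE, identifiable = TRUE, rss = NA_real_,
              auc = NA_real_)
  class(out) <- "kinetic_fit"

  if (all(cc == 0)) {
    # flat-zero curve: plateau 0, rate not identifiable
    out$calpha <- 0; out$k <- NA_real_
    out$converged <- TRUE; out$identifiable <- FALSE
    out$rss <- 0; out$auc <- 0
    return(out)
  }

  # the model is linear in Calpha given k, so Calpha is profiled out
  # analytically and the search is 1-D over k (bounded, log-spaced grid
  # bracketing + golden-section refinement)
  ca_of_k <- function(k) {
    f <- 1 - exp(-k * tt)
    min(max(sum(cc * f) / sum(f * f), 0), 110)
  }
  if (calpha == "plugin") ca_of_k <- function(k) cc[length(cc)]
  rss_of_k <- function(k) {
    pred <- ca_of_k(k) * (1 - exp(-k * tt))
    sum((cc - pred)^2)
  }
  klo <- 1e-6; khi <- 1
  grid <- exp(seq(log(klo), log(khi), length.out = 80))
  rg <- vapply(grid, rss_of_k, numeric(1))
  i <- which.min(rg)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  op <- stats::optimize(rss_of_k, interval = c(lo, hi), tol = 1e-12)

  out$k <- op$minimum
  out$calpha <- ca_of_k(op$minimum)
  out$rss <- op$objective
  out$converged <- TRUE
  # k pinned at the search boundary means the plateau was not resolved
  out$identifiable <- out$calpha > 0 && out$k > klo * 2 && out$k < khi * 0.999
  out$auc <- auc_first_order(out$calpha, max(out$k, klo), 0,
                             max(max(curve$times), 180))
  out
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %s: Calpha=%.3f%%, k=%.5f/min, AUC=%.1f (converged=%s)\n",
              x$sample, x$calpha, x$k, x$auc, x$converged))
  invisible(x)
}

#' Closed-form area under the first-order hydrolysis curve
#'
#' For `C(t) = Calpha (1 - exp(-k t))`, the area over `[t0, tf]` measured from
#' the start of incubation is
#' `Calpha * (tf - t0) - (Calpha / k) * (1 - exp(-k * (tf - t0)))`.
#'
#' @param calpha Equilibrium percent starch hydrolyzed (>= 0).
#' @param k Kinetic constant per minute (> 0).
#' @param t0,tf Initial and final times in minutes; defaults 0 and 180.
#' @return The area (percent-minutes).
#' @export
auc_first_order <- function(calpha, k, t0 = 0, tf = 180) {
  if (any(k <= 0)) stop("k must be positive")
  if (any(tf <= t0) || any(t0 < 0)) stop("need tf > t0 >= 0")
  if (any(calpha < 0)) stop("calpha must be non-negative")
  dt <- tf - t0
  calpha * dt - (calpha / k) * (1 - exp(-k * dt))
}

#' Hydrolysis index relative to a reference food
#'
#' HI is the sample's hydrolysis-curve area as a percent of the reference
#' (white bread) area: `100 * auc_sample / auc_reference`.  The percent
#' convention is required for the downstream PGI mapping to span realistic
#' values.
#'
#' @param auc_sample Sample AUC (>= 0).
#' @param auc_reference Reference AUC (> 0).
#' @return HI in percent.
#' @export
hydrolysis_index <- function(auc_sample, auc_reference) {
  if (any(!is.finite(auc_reference)) || any(auc_reference <= 0))
    stop("auc_reference must be positive")
  if (any(auc_sample < 0)) stop("auc_sample must be non-negative")
  100 * auc_sample / auc_reference
}

#' Predicted glycemic index from the hydrolysis index
#'
#' Linear calibration of in-vitro hydrolysis against in-vivo glycemic
#' response: `PGI = 39.7 + 0.548 * HI`.
#'
#' @param hi Hydrolysis index in percent (>= 0).
#' @return Predicted glycemic index.
#' @examples
#' predicted_gi(0)    # 39.7
#' predicted_gi(100)  # 94.5
#' @export
predicted_gi <- function(hi) {
  if (any(!is.finite(hi) | hi < 0)) stop("hi must be finite and non-negative")
  39.7 + 0.548 * hi
}

#' Classify a predicted glycemic index
#'
#' Conventional GI banding: low below 55, intermediate 55-70, high above 70.
#'
#' @param pgi Numeric vector of predicted glycemic index values.
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @export
classify_gi <- function(pgi) {
  if (any(!is.finite(pgi))) stop("pgi must be finite")
  cls <- ifelse(pgi < 55, "low", ifelse(pgi <= 70, "intermediate", "high"))
  factor(cls, levels = c("low", "intermediate", "high"))
}

#' Resistant starch percent from a GOPOD assay read-out
#'
#' Converts a glucose-oxidase/peroxidase (GOPOD) absorbance read-out into
#' percent resistant starch on a dry-mass basis.  Released glucose mass is
#' `(absorbance_sample - absorbance_blank) * gopod_factor * dilution`
#' (micrograms), and
#' `RS% = glucose_ug * 0.9 / (sample_mass_mg * 1000) * 100`.
#' The same arithmetic applied to the pooled-supernatant read-out gives the
#' non-resistant (solubilized) fraction.  Negative net absorbances are clamped
#' to zero with a warning.
#'
#' @param absorbance_sample,absorbance_blank Absorbance of sample and reagent
#'   blank.
#' @param gopod_factor Micrograms of glucose per absorbance unit, from the
#'   D-glucose standard.
#' @param dilution Combined volumetric dilution factor of the assay (the kit's
#'   volume corrections, exposed explicitly).
#' @param sample_mass_mg Sample dry mass in milligrams (> 0).
#' @return RS (or non-RS) content in percent of sample mass.
#' @export
rs_percent <- function(absorbance_sample, absorbance_blank, gopod_factor,
                       dilution = 1, sample_mass_mg = 100) {
  if (any(sample_mass_mg <= 0)) stop("sample_mass_mg must be positive")
  if (any(gopod_factor <= 0)) stop("gopod_factor must be positive")
  net <- absorbance_sample - absorbance_blank
  if (any(net < 0)) {
    warning("negative net absorbance clamped to 0")
    net <- pmax(net, 0)
  }
  glucose_ug <- net * gopod_factor * dilution
  starch_from_glucose(glucose_ug) / (sample_mass_mg * 1000) * 100
}

#' PGI pipeline over a table of hydrolysis curves
#'
#' Chains [fit_first_order()], [auc_first_order()], [hydrolysis_index()],
#' [predicted_gi()] and [classify_gi()] over a set of curves, using either a
#' designated reference curve or a precomputed reference AUC.
#'
#' @param curves List of [hydrolysis_curve()] objects.
#' @param reference Either the sample id of the reference (white-bread) curve
#'   in `curves`, or a single positive number taken as the reference AUC.
#' @param t0,tf Integration bounds in minutes (defaults 0, 180).
#' @return `data.frame` with columns `sample`, `calpha`, `k`, `auc`, `hi`,
#'   `pgi`, `gi_class`.
#' @export
pgi_pipeline <- function(curves, reference, t0 = 0, tf = 180) {
  stopifnot(length(curves) >= 1)
  fits <- lapply(curves, fit_first_order)
  auc <- vapply(fits, function(f)
    if (is.na(f$k)) 0 else auc_first_order(f$calpha, f$k, t0, tf), numeric(1))
  ids <- vapply(fits, `[[`, character(1), "sample")
  if (is.numeric(reference)) {
    ref_auc <- reference
  } else {
    i <- match(reference, ids)
    if (is.na(i)) stop("reference sample '", reference, "' not found")
    ref_auc <- auc[i]
  }
  hi <- hydrolysis_index(auc, ref_auc)
  pgi <- predicted_gi(hi)
  data.frame(sample = ids,
             calpha = vapply(fits, `[[`, numeric(1), "calpha"),
             k = vapply(fits, `[[`, numeric(1), "k"),
             auc = auc, hi = hi, pgi = pgi,
             gi_class = classify_gi(pgi),
             stringsAsFactors = FALSE)
}

#' Read hydrolysis curves from CSV
#'
#' Expected columns: `sample`, `time_30` ... `time_180` (glucose readings at
#' the minute encoded in the column name), `total_starch`, and optionally a
#' logical/0-1 `reference` column flagging the white-bread reference sample.
#'
#' @param path CSV file path.
#' @return List with `curves` (list of [hydrolysis_curve()]) and `reference`
#'   (sample id or NULL).
#' @export
read_curves_csv <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  tcols <- grep("^time_\\d+$", names(df), value = TRUE)
  if (length(tcols) < 3) stop("need at least 3 time_<minutes> columns")
  times <- as.numeric(sub("^time_", "", tcols))
  ord <- order(times)
  curves <- lapply(seq_len(nrow(df)), function(i)
    hydrolysis_curve(df$sample[i], times[ord],
                     as.numeric(df[i, tcols[ord]]),
                     if ("total_starch" %in% names(df)) df$total_starch[i] else 100))
  ref <- NULL
  if ("reference" %in% names(df) && any(as.logical(df$reference)))
    ref <- df$sample[which(as.logical(df$reference))[1]]
  list(curves = curves, reference = ref)
}
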