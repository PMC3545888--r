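# Absolute qPCR quantification and replication-kinetics arithmetic.
#
# A standard curve is an ordinary least-squares fit of Ct on log10(copies);
# amplification efficiency is 10^(-1/slope) - 1 (so slope -3.3219 means a
# perfect doubling per cycle).  Sample copy numbers are the curve inverse,
# viral copies are normalised per 1e5 host actin copies, and growth phases
# are annotated from per-interval log2 rates.

#' Fit a qPCR standard curve
#'
#' @param log10_copies log10 copy numbers of the dilution points (at least 3
#'   distinct values).
#' @param ct matching Ct values: a numeric vector of triplicate means, or a
#'   matrix/data frame with one row per dilution point whose columns are
#'   replicates (averaged on the Ct scale).
#' @return object of class \code{standard_curve}: \code{slope} (Ct per
#'   log10 copies), \code{intercept}, \code{r_squared}, \code{efficiency}.
#'   A warning is given if efficiency falls outside [0.8, 1.1].
#' @export
fit_standard_curve <- function(log10_copies, ct) {
    if (is.matrix(ct) || is.data.frame(ct)) ct <- rowMeans(as.matrix(ct))
    stopifnot(length(ct) == length(log10_copies))
    if (length(log10_copies) < 3L) stop("at least 3 dilution points required")
    if (length(unique(log10_copies)) < 2L) stop("zero variance in copy numbers")
    fit <- lm(ct ~ log10_copies)
    slope <- unname(coef(fit)[2L])
    if (slope >= 0) warning("non-negative slope: dilution series looks inverted")
    eff <- 10^(-1 / slope) - 1
    if (!is.na(eff) && (eff < 0.8 || eff > 1.1)) {
        warning(sprintf("amplification efficiency %.2f outside [0.8, 1.1]", eff))
    }
    # r^2 computed directly (summary.lm warns on an exactly collinear fit)
    r2 <- 1 - sum(fit$residuals^2) / sum((ct - mean(ct))^2)
    structure(list(slope = slope, intercept = unname(coef(fit)[1L]),
                   r_squared = r2, efficiency = eff),
              class = "standard_curve")
}

#' Absolute copy number from a Ct value
#'
#' @param curve a \code{\link{fit_standard_curve}} result.
#' @param ct Ct value(s).
#' @return copies = 10^((ct - intercept) / slope).
#' @export
quantify <- function(curve, ct) {
    stopifnot(inherits(curve, "standard_curve"))
    10^((ct - curve$intercept) / curve$slope)
}

#' Normalise viral copies against host actin copies
#'
#' @param viral_copies,actin_copies equal-length, time-matched copy numbers.
#' @param times time points in hours post infection.
#' @param per reporting denominator (default 1e5 actin copies).
#' @return object of class \code{normalized_series}: \code{times},
#'   \code{values} (viral copies per \code{per} actin copies),
#'   \code{phase_labels} (NULL until \code{\link{annotate_phases}}).
#' @export
normalize_copies <- function(viral_copies, actin_copies, times, per = 1e5) {
    stopifnot(length(viral_copies) == length(actin_copies),
              length(times) == length(viral_copies))
    if (any(actin_copies <= 0)) {
        stop("zero or negative actin copies at time point(s): ",
             paste(times[actin_copies <= 0], collapse = ", "))
    }
    structure(list(times = times, values = viral_copies / actin_copies * per,
                   phase_labels = NULL),
              class = "normalized_series")
}

#' Annotate growth phases of a normalised series
#'
#' Each interval between consecutive time points gets a label from its log2
#' rate r = d log2(value) / dt: \code{exponential} if r >= \code{expo};
#' \code{decreasing} if r < -\code{eps}; after the last exponential interval,
#' any 0 < r < \code{expo} is \code{stationary}; everything else is
#' \code{latent}.
#'
#' @param series a \code{normalized_series} with at least 3 time points.
#' @param eps_log2_per_h rate below which growth counts as flat (default
#'   0.05 log2/h).
#' @param expo_log2_per_h rate at or above which an interval is exponential
#'   (default 0.5 log2/h).
#' @return the series with \code{phase_labels} (length = intervals) and
#'   \code{rates} filled in.
#' @export
annotate_phases <- function(series, eps_log2_per_h = 0.05, expo_log2_per_h = 0.5) {
    stopifnot(inherits(series, "normalized_series"))
    t <- series$times; v <- series$values
    if (length(t) < 3L) stop("at least 3 time points required")
    if (any(diff(t) <= 0)) stop("times must be strictly increasing")
    if (any(v <= 0)) stop("values must be positive")
    r <- diff(log2(v)) / diff(t)
    lab <- rep("latent", length(r))
    lab[r >= expo_log2_per_h] <- "exponential"
    lab[r < -eps_log2_per_h] <- "decreasing"
    last_expo <- if (any(lab == "exponential")) max(which(lab == "exponential")) else 0L
    if (last_expo > 0L && last_expo < length(r)) {
        after <- (last_expo + 1L):length(r)
        stat <- after[r[after] > 0 & r[after] < expo_log2_per_h]
        lab[stat] <- "stationary"
    }
    series$phase_labels <- lab
    series$rates <- r
    series
}

#' Fold change, doublings and doubling time over a window
#'
#' @param series a \code{normalized_series}.
#' @param window two time points (present in the series) bounding the window.
#' @return object of class \code{kinetics_summary}: \code{fold_change},
#'   \code{doublings} = log2(fold), \code{doubling_time} = window /
#'   doublings (NA when fold = 1), plus \code{doublings_rounded} and
#'   \code{doubling_time_rounded} based on the nearest-integer doubling count.
#' @export
kinetics_summary <- function(series, window) {
    stopifnot(inherits(series, "normalized_series"), length(window) == 2L)
    i1 <- match(window[1L], series$times)
    i2 <- match(window[2L], series$times)
    if (is.na(i1) || is.na(i2)) stop("window endpoints must be time points of the series")
    v1 <- series$values[i1]; v2 <- series$values[i2]
    if (v1 == 0) stop("value at window start is zero")
    fold <- v2 / v1
    dbl <- log2(fold)
    dt <- window[2L] - window[1L]
    dbl_r <- round(dbl)
    structure(list(fold_change = fold, doublings = dbl,
                   doubling_time = if (dbl == 0) NA_real_ else dt / dbl,
                   doublings_rounded = dbl_r,
                   doubling_time_rounded = if (dbl_r == 0) NA_real_ else dt / dbl_r),
              class = "kinetics_summary")
}

#' Run the full qPCR quantification pipeline
#'
#' Fits per-target standard curves, quantifies triplicate sample Cts
#' (averaged on the Ct scale), and normalises the viral target against the
#' host actin target.
#'
#' @param standards data frame: \code{target}, \code{log10_copies},
#'   \code{ct_1}, \code{ct_2}, \code{ct_3}.
#' @param samples data frame: \code{time_h}, \code{target}, \code{ct_1},
#'   \code{ct_2}, \code{ct_3}.
#' @param viral_target,actin_target target names (defaults "rr2b", "actin").
#' @param per reporting denominator (default 1e5).
#' @return a \code{normalized_series}; attribute \code{curves} carries the
#'   fitted standard curves.
#' @export
analyze_qpcr <- function(standards, samples, viral_target = "rr2b",
                         actin_target = "actin", per = 1e5) {
    ct_cols <- grep("^ct_", names(standards), value = TRUE)
    curves <- lapply(split(standards, standards$target), function(d) {
        fit_standard_curve(d$log10_copies, as.matrix(d[ct_cols]))
    })
    for (tg in c(viral_target, actin_target)) {
        if (is.null(curves[[tg]])) stop("no standards for target '", tg, "'")
    }
    ct_cols_s <- grep("^ct_", names(samples), value = TRUE)
    samples$ct_mean <- rowMeans(as.matrix(samples[ct_cols_s]))
    get <- function(tg) {
        d <- samples[samples$target == tg, , drop = FALSE]
        d <- d[order(d$time_h), , drop = FALSE]
        d$copies <- quantify(curves[[tg]], d$ct_mean)
        d
    }
    vir <- get(viral_target); act <- get(actin_target)
    if (!identical(vir$time_h, act$time_h)) {
        stop("viral and actin samples are not time-matched")
    }
    out <- normalize_copies(vir$copies, act$copies, vir$time_h, per = per)
    attr(out, "curves") <- curves
    out
}
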