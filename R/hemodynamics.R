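#' Maximal rate of LV pressure rise, dP/dt_max
#'
#' Per-beat maximum of the centered-difference pressure derivative. Beats
#' are delimited by pressure-minimum detection: the trace is segmented at
#' upward crossings of its mid-pressure level and each boundary refined to
#' the pressure minimum of the preceding interval. Ectopic beats -- per-beat
#' dP/dt_max further than 3 robust standard deviations (median-centered,
#' MAD-scaled) from the window's beats -- are excluded before averaging;
#' the robust scale keeps several simultaneous ectopics in a short window
#' from masking each other.
#'
#' @param trace Tibble with `time_s` (uniform sampling of at least 100 Hz
#'   over a window of at least 10 s) and `pressure_mmhg`.
#' @return A list: `dpdt_mean` (mmHg/s over retained beats), `beats` (tibble
#'   with `beat`, `dpdt_max`, `retained`), `n_beats`.
#' @export
#' @examples
#' tr <- tibble::tibble(
#'   time_s = seq(0, 12, by = 1 / 500),
#'   pressure_mmhg = 50 + 50 * sin(2 * pi * seq(0, 12, by = 1 / 500))
#' )
#' dpdt_max(tr)$dpdt_mean # ~ 100 * pi
dpdt_max <- function(trace) {
  stopifnot(is.data.frame(trace), all(c("time_s", "pressure_mmhg") %in% names(trace)))
  t <- trace$time_s
  p <- trace$pressure_mmhg
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-6) stop("trace must be uniformly sampled")
  fs <- 1 / dt[1]
  if (fs < 100) stop("sampling rate must be at least 100 Hz")
  if (t[length(t)] - t[1] < 10) stop("window must cover at least 10 s")

  n <- length(p)
  deriv <- c(NA, (p[3:n] - p[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)]), NA)

  # robust mid-level: quantiles keep a single large ectopic beat from
  # lifting the threshold above the normal systolic peaks
  q <- stats::quantile(p, c(0.05, 0.95), names = FALSE)
  mid <- (q[1] + q[2]) / 2
  up <- which(p[-1] >= mid & p[-n] < mid) + 1L
  if (length(up) < 4) stop("fewer than 3 beats detected")
  # refine boundaries to the pressure minimum between consecutive upcrossings
  bounds <- vapply(seq_len(length(up) - 1), function(i) {
    seg <- up[i]:up[i + 1]
    seg[which.min(p[seg])]
  }, integer(1))
  if (length(bounds) < 4) stop("fewer than 3 beats detected")

  beat_dpdt <- vapply(seq_len(length(bounds) - 1), function(i) {
    idx <- bounds[i]:bounds[i + 1]
    max(deriv[idx], na.rm = TRUE)
  }, numeric(1))

  # 3-sigma exclusion with robust scale (median / MAD): a mean/SD rule is
  # masked when several ectopics land in one short window
  center <- stats::median(beat_dpdt)
  sigma <- max(stats::mad(beat_dpdt), 0.002 * abs(center), 1e-9)
  retained <- abs(beat_dpdt - center) <= 3 * sigma
  if (sum(retained) < 3) stop("fewer than 3 beats retained")

  list(
    dpdt_mean = mean(beat_dpdt[retained]),
    beats = tibble::tibble(beat = seq_along(beat_dpdt),
                           dpdt_max = beat_dpdt, retained = retained),
    n_beats = length(beat_dpdt)
  )
}

#' Acute hemodynamic response (AHR)
#'
#' Percent change from the reference dP/dt_max to the mean biventricular
#' paced dP/dt_max: `100 * (paced - baseline) / baseline`. Negative values
#' are allowed.
#'
#' @param baseline_dpdt Reference dP/dt_max (mmHg/s, > 0).
#' @param paced_dpdt Mean biventricular dP/dt_max (mmHg/s).
#' @return AHR in percent.
#' @export
compute_ahr <- function(baseline_dpdt, paced_dpdt) {
  if (any(baseline_dpdt <= 0)) stop("baseline dP/dt_max must be positive")
  100 * (paced_dpdt - baseline_dpdt) / baseline_dpdt
}

#' Group comparison of AHR between target and non-target segments
#'
#' Pools tested segments and compares AHR between target and non-target
#' groups with a two-sided Welch (unequal-variance) t test (`paired = TRUE`
#' switches to the paired test on patient-matched values), and compares the
#' proportions with AHR > `ahr_cut` (default 10 %) with the Fisher exact
#' test. The scarred subgroup mean is reported separately, as is the
#' viable (non-scarred) non-target subgroup.
#'
#' @param records Tibble with one row per tested segment: `ahr`, `group`
#'   (`"target"` / `"nontarget"`), `class` (`"target"`,
#'   `"nontarget_viable"`, `"scarred"`), optionally `capture` (rows with
#'   `capture = FALSE` are dropped).
#' @param ahr_cut Threshold (%) for the responder proportion (default 10).
#' @param paired Use a paired t test (requires a `patient` column and equal
#'   group sizes per patient); default unpaired Welch.
#' @return An object of class `ahr_comparison`; see [tidy.ahr_comparison()]
#'   and [glance.ahr_comparison()].
#' @export
compare_groups <- function(records, ahr_cut = 10, paired = FALSE) {
  stopifnot(all(c("ahr", "group", "class") %in% names(records)))
  if ("capture" %in% names(records)) {
    records <- records[isTRUE_vec(records$capture), , drop = FALSE]
  }
  records <- records[!is.na(records$ahr), , drop = FALSE]
  tg <- records$ahr[records$group == "target"]
  nt <- records$ahr[records$group == "nontarget"]
  if (length(tg) < 2 || length(nt) < 2) stop("need at least 2 records per group")

  tt <- if (paired) {
    stats::t.test(tg, nt, paired = TRUE)
  } else {
    stats::t.test(tg, nt, var.equal = FALSE)
  }
  tab <- rbind(
    target = c(sum(tg > ahr_cut), sum(tg <= ahr_cut)),
    nontarget = c(sum(nt > ahr_cut), sum(nt <= ahr_cut))
  )
  fish <- stats::fisher.test(tab)

  sub_stats <- function(x) c(mean = mean(x), sd = stats::sd(x), n = length(x),
                             prop_gt = mean(x > ahr_cut))
  sc <- records$ahr[records$class == "scarred"]
  nv <- records$ahr[records$class == "nontarget_viable" & records$group == "nontarget"]

  structure(
    list(
      target = sub_stats(tg), nontarget = sub_stats(nt),
      nontarget_viable = if (length(nv)) sub_stats(nv) else NULL,
      scarred = if (length(sc)) sub_stats(sc) else NULL,
      t_test = tt, fisher = fish, table = tab, ahr_cut = ahr_cut,
      paired = paired
    ),
    class = "ahr_comparison"
  )
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.ahr_comparison <- function(x, ...) {
  cat("AHR group comparison (", if (x$paired) "paired t" else "Welch t",
      " + Fisher exact at >", x$ahr_cut, "%)\n", sep = "")
  print(tidy(x))
  cat(sprintf("t test p = %.4g; Fisher p = %.4g\n",
              x$t_test$p.value, x$fisher$p.value))
  invisible(x)
}

#' Tidy an AHR group comparison
#'
#' @param x An `ahr_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return One row per group/subgroup with `group`, `mean`, `sd`, `n`,
#'   `prop_gt_cut`.
#' @export
tidy.ahr_comparison <- function(x, ...) {
  rows <- purrr::compact(list(
    target = x$target, nontarget = x$nontarget,
    nontarget_viable = x$nontarget_viable, scarred = x$scarred
  ))
  tibble::tibble(
    group = names(rows),
    mean = vapply(rows, `[[`, numeric(1), "mean"),
    sd = vapply(rows, `[[`, numeric(1), "sd"),
    n = as.integer(vapply(rows, `[[`, numeric(1), "n")),
    prop_gt_cut = vapply(rows, `[[`, numeric(1), "prop_gt")
  )
}

#' One-row summary of an AHR group comparison
#'
#' @inheritParams tidy.ahr_comparison
#' @return A one-row tibble: group means, mean difference, t statistic and
#'   p value, Fisher p value.
#' @export
glance.ahr_comparison <- function(x, ...) {
  tibble::tibble(
    target_mean = x$target[["mean"]],
    nontarget_mean = x$nontarget[["mean"]],
    mean_difference = x$target[["mean"]] - x$nontarget[["mean"]],
    statistic = unname(x$t_test$statistic),
    p_value = x$t_test$p.value,
    fisher_p_value = x$fisher$p.value
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
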