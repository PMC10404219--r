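# Behavioral indices for the lateralized change-detection working-memory
# task, plus a generative signal-detection simulator so every index is
# testable without participant data.
#
# Session structure: 120 trials in 6 blocks of 20, one memory load (4, 5
# or 6 items) per block and two blocks per load; each block holds 10 left-
# and 10 right-hemifield trials, 5 match and 5 mismatch per hemifield.
# Signal-detection convention: the "signal" is a match trial, so a hit is
# responding "same" on a match trial and a false alarm is responding
# "same" on a mismatch trial; d' is symmetric under the opposite mapping.

#' Session design constants
#'
#' @return list describing the standard session: 6 blocks of 20 trials,
#'   loads 4/5/6 (two blocks each), 10/10 hemifield split and 5/5
#'   match/mismatch split per hemifield.
#' @export
session_design <- function() {
  list(blocks = 6L, trials_per_block = 20L, loads = c(4L, 5L, 6L),
       blocks_per_load = 2L, per_hemifield = 10L, per_truth = 5L,
       total_trials = 120L)
}

#' Working-memory capacity K
#'
#' `K = load * (accuracy - miss_rate)`.  Accuracy and miss rate are
#' literal proportions over all trials of the load-by-hemifield cell
#' (see [session_indices()] for the configurable denominators); K may be
#' negative for poor performance and is not clipped.
#'
#' @param load memory load (items).
#' @param accuracy proportion correct in \[0, 1\].
#' @param miss_rate proportion of misses in \[0, 1\].
#' @return capacity estimate in items.
#' @examples
#' k_value(4, 0.75, 0.10) # 2.6
#' @export
k_value <- function(load, accuracy, miss_rate) {
  if (any(accuracy < 0 | accuracy > 1 | miss_rate < 0 | miss_rate > 1)) {
    abort("rates must lie in [0, 1]")
  }
  load * (accuracy - miss_rate)
}

#' Signal-detection sensitivity d'
#'
#' `d' = qnorm(hit rate) - qnorm(false-alarm rate)` after extreme-rate
#' correction: rates of 0 are replaced by `1/(2N)` and rates of 1 by
#' `1 - 1/(2N)` with N the trial count behind the rate (`correction =
#' "proportion"`, the default), or all counts are shifted by 0.5 with N+1
#' in the denominator (`"loglinear"`).
#'
#' @param hit_rate hit rate (hits / match trials).
#' @param fa_rate false-alarm rate (false alarms / mismatch trials).
#' @param n_match,n_mismatch trial counts behind the two rates.
#' @param correction `"proportion"` or `"loglinear"`.
#' @return d' (dimensionless, finite).
#' @examples
#' dprime(0.69146, 0.30854, 100, 100) # ~1
#' @export
dprime <- function(hit_rate, fa_rate, n_match, n_mismatch,
                   correction = c("proportion", "loglinear")) {
  correction <- match.arg(correction)
  if (any(c(n_match, n_mismatch) <= 0)) abort("trial counts must be > 0")
  if (correction == "proportion") {
    h <- pmin(pmax(hit_rate, 1 / (2 * n_match)), 1 - 1 / (2 * n_match))
    f <- pmin(pmax(fa_rate, 1 / (2 * n_mismatch)), 1 - 1 / (2 * n_mismatch))
  } else {
    h <- (hit_rate * n_match + 0.5) / (n_match + 1)
    f <- (fa_rate * n_mismatch + 0.5) / (n_mismatch + 1)
  }
  stats::qnorm(h) - stats::qnorm(f)
}

#' Load-weighted average d'
#'
#' d' computed per load, multiplied by the corresponding load, then
#' averaged: `mean(load * dprime(load))`.
#'
#' @param per_load_dprimes d' values, one per load.
#' @param loads the corresponding loads.
#' @return the load-weighted average.
#' @examples
#' weighted_dprime(c(1, 1, 1), c(4, 5, 6)) # 5
#' @export
weighted_dprime <- function(per_load_dprimes, loads) {
  if (length(per_load_dprimes) != length(loads)) {
    abort("d' values and loads must align")
  }
  mean(per_load_dprimes * loads)
}

#' Lateralization index
#'
#' `LI = (M_R - M_L) / (M_R + M_L)`: positive values indicate a
#' right-hemifield performance advantage.
#'
#' @param m_right,m_left hemifield measurements (K or weighted d').
#' @return LI in \[-1, 1\] for nonnegative measurements; `NA` (with a
#'   warning) when the denominator is zero.
#' @examples
#' lateralization_index(3, 1) # 0.5
#' @export
lateralization_index <- function(m_right, m_left) {
  den <- m_right + m_left
  out <- ifelse(den == 0, NA_real_, (m_right - m_left) / den)
  if (any(den == 0)) warning("zero denominator: LI undefined", call. = FALSE)
  out
}

#' Median split into low/high LI groups
#'
#' Subjects strictly below the median form the low group; subjects at or
#' above the median (ties included) form the high group.
#'
#' @param per_subject_li numeric vector of per-subject LIs (length >= 2).
#' @return factor with levels `low`, `high`.
#' @export
median_split <- function(per_subject_li) {
  if (length(per_subject_li) < 2) abort("need at least 2 subjects")
  med <- stats::median(per_subject_li)
  factor(ifelse(per_subject_li < med, "low", "high"),
         levels = c("low", "high"))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone in rank, capped at 1), computed
#' through `stats::p.adjust(method = "BH")` after range validation.
#'
#' @param p_values p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Simulate one change-detection session
#'
#' Draws responses from the equal-variance Gaussian signal-detection
#' model: match trials carry evidence `N(d', 1)` and mismatch trials
#' `N(0, 1)` for the hemifield's d'; the subject responds "same" when the
#' evidence exceeds `d'/2 + criterion`.  With probability `lapse_rate`
#' the response is replaced by a random guess.  Trial counts follow
#' [session_design()] exactly and the draw is deterministic per seed.
#'
#' @param design output of [session_design()].
#' @param dprime_left,dprime_right generating sensitivities (>= 0).
#' @param criterion response bias (0 = unbiased).
#' @param lapse_rate guessing probability in \[0, 0.2\].
#' @param seed integer seed (the caller's RNG state is preserved).
#' @return data frame with `block`, `load`, `hemifield`, `truth`,
#'   `response`.
#' @export
simulate_session <- function(design = session_design(),
                             dprime_left = 1.5, dprime_right = 1.5,
                             criterion = 0, lapse_rate = 0, seed = 1L) {
  if (any(c(dprime_left, dprime_right) < 0)) abort("d' must be >= 0")
  if (lapse_rate < 0 || lapse_rate > 0.2) abort("lapse_rate must be in [0, 0.2]")
  with_seed(seed, {
    loads <- sample(rep(design$loads, design$blocks_per_load))
    rows <- lapply(seq_len(design$blocks), function(b) {
      hemi <- sample(rep(c("left", "right"), each = design$per_hemifield))
      truth <- unlist(lapply(c("left", "right"), function(h) {
        sample(rep(c("match", "mismatch"), each = design$per_truth))
      }))
      # truth drawn per hemifield, align to the shuffled hemifield order
      tr <- character(design$trials_per_block)
      tr[hemi == "left"] <- truth[1:design$per_hemifield]
      tr[hemi == "right"] <- truth[design$per_hemifield + 1:design$per_hemifield]
      data.frame(block = b, load = loads[b], hemifield = hemi,
                 truth = tr, stringsAsFactors = FALSE)
    })
    trials <- do.call(rbind, rows)
    dp <- ifelse(trials$hemifield == "left", dprime_left, dprime_right)
    evidence <- stats::rnorm(nrow(trials),
                             mean = ifelse(trials$truth == "match", dp, 0))
    resp <- ifelse(evidence > dp / 2 + criterion, "same", "different")
    lapse <- stats::runif(nrow(trials)) < lapse_rate
    resp[lapse] <- sample(c("same", "different"), sum(lapse), replace = TRUE)
    trials$response <- resp
    trials
  })
}

#' Signal-detection counts per load and hemifield
#'
#' @param trials a trial table with columns `load`, `hemifield`, `truth`
#'   (`match`/`mismatch`) and `response` (`same`/`different`/`none`).
#' @return data frame with one row per load-by-hemifield cell: trial
#'   counts, hits, misses, false alarms, correct rejections, omissions.
#' @export
sdt_counts <- function(trials) {
  need <- c("load", "hemifield", "truth", "response")
  if (!all(need %in% names(trials))) {
    abort("trial table needs columns %s", paste(need, collapse = ", "))
  }
  cells <- unique(trials[, c("load", "hemifield")])
  cells <- cells[order(cells$load, cells$hemifield), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    d <- trials[trials$load == cells$load[i] &
                  trials$hemifield == cells$hemifield[i], ]
    m <- d$truth == "match"
    data.frame(
      load = cells$load[i], hemifield = cells$hemifield[i],
      n = nrow(d), n_match = sum(m), n_mismatch = sum(!m),
      hits = sum(m & d$response == "same"),
      misses = sum(m & d$response == "different"),
      false_alarms = sum(!m & d$response == "same"),
      correct_rejections = sum(!m & d$response == "different"),
      omissions = sum(d$response == "none")
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-hemifield behavioral indices of a session
#'
#' Computes, per hemifield: the across-load mean K value, the
#' load-weighted average d', and from those the two lateralization
#' indices.  Accuracy is `(hits + correct rejections) / n` and the
#' default miss rate is `misses / n` over all trials of the cell
#' (`miss_denominator = "all"`); the alternative `"match"` uses
#' `misses / match trials`.  `k_form = "cowan"` switches K to
#' `load * (hit rate - false-alarm rate)`.  Omitted responses count as
#' errors and are reported separately.
#'
#' @param trials a trial table (see [sdt_counts()]).
#' @param miss_denominator `"all"` (default) or `"match"`.
#' @param k_form `"printed"` (`load * (accuracy - miss rate)`, default)
#'   or `"cowan"`.
#' @param dprime_correction passed to [dprime()].
#' @return list with `per_cell` (data frame), `per_hemifield` (K and
#'   weighted d' per hemifield), `li` (named: `K`, `dprime`) and the
#'   choices recorded in `options`.
#' @export
session_indices <- function(trials, miss_denominator = c("all", "match"),
                            k_form = c("printed", "cowan"),
                            dprime_correction = "proportion") {
  miss_denominator <- match.arg(miss_denominator)
  k_form <- match.arg(k_form)
  cc <- sdt_counts(trials)
  cc$accuracy <- (cc$hits + cc$correct_rejections) / cc$n
  cc$miss_rate <- cc$misses /
    if (miss_denominator == "all") cc$n else cc$n_match
  cc$hit_rate <- cc$hits / cc$n_match
  cc$fa_rate <- cc$false_alarms / cc$n_mismatch
  cc$K <- if (k_form == "printed") {
    k_value(cc$load, cc$accuracy, cc$miss_rate)
  } else {
    cc$load * (cc$hit_rate - cc$fa_rate)
  }
  cc$dprime <- dprime(cc$hit_rate, cc$fa_rate, cc$n_match, cc$n_mismatch,
                      correction = dprime_correction)
  hemi <- lapply(split(cc, cc$hemifield), function(d) {
    d <- d[order(d$load), ]
    data.frame(hemifield = d$hemifield[1],
               K = mean(d$K),
               weighted_dprime = weighted_dprime(d$dprime, d$load),
               omissions = sum(d$omissions))
  })
  hemi <- do.call(rbind, hemi)
  rownames(hemi) <- NULL
  gk <- function(h, col) hemi[hemi$hemifield == h, col]
  li <- c(
    K = lateralization_index(gk("right", "K"), gk("left", "K")),
    dprime = lateralization_index(gk("right", "weighted_dprime"),
                                  gk("left", "weighted_dprime"))
  )
  list(per_cell = cc, per_hemifield = hemi, li = li,
       options = list(miss_denominator = miss_denominator, k_form = k_form,
                      dprime_correction = dprime_correction))
}

#' Simulate and pool multiple sessions
#'
#' @inheritParams simulate_session
#' @param n_sessions number of sessions to pool.
#' @param seed base seed; session s uses `seed + s - 1`.
#' @return pooled trial table.
#' @export
simulate_sessions <- function(n_sessions, design = session_design(),
                              dprime_left = 1.5, dprime_right = 1.5,
                              criterion = 0, lapse_rate = 0, seed = 1L) {
  do.call(rbind, lapply(seq_len(n_sessions), function(s) {
    tr <- simulate_session(design, dprime_left, dprime_right,
                           criterion, lapse_rate, seed = seed + s - 1L)
    tr$session <- s
    tr
  }))
}

#' Read / write trial tables
#'
#' CSV with columns `subject,condition,block,load,hemifield,truth,response`
#' (extra columns preserved).
#'
#' @param path CSV path.
#' @return data frame of trials.
#' @export
read_trials_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_trials_csv
#' @param trials trial table.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}
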