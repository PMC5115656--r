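# The statistical layer: Pearson correlations with significance,
# mean +/- sd summaries, activity rankings with tied groups, and the
# printed-table consistency re-computation.

#' Pearson product-moment correlation with significance
#'
#' Computed directly from the product-moment formula; the two-sided
#' p-value comes from the t transform `t = r * sqrt((n-2)/(1-r^2))` with
#' n-2 degrees of freedom. Exclusions (e.g. a compound whose computed
#' value is a known outlier) are explicit arguments, never hard-coded.
#'
#' @param x,y numeric vectors of equal length (n >= 3 after exclusions).
#' @param labels optional labels parallel to `x`/`y`.
#' @param exclude labels (or indices when `labels` is `NULL`) to drop
#'   before computing.
#' @return list with `r`, `n`, `p_two_sided`, `excluded`.
#' @export
pearson_r <- function(x, y, labels = NULL, exclude = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  drop_idx <- integer()
  if (!is.null(exclude)) {
    drop_idx <- if (is.null(labels)) as.integer(exclude) else which(labels %in% exclude)
  }
  if (length(drop_idx) > 0) {
    x <- x[-drop_idx]
    y <- y[-drop_idx]
  }
  n <- length(x)
  if (n < 3) stop("need at least 3 points for a correlation", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in correlation input", call. = FALSE)
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) stop("zero variance in correlation input", call. = FALSE)
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  list(r = r, n = n, p_two_sided = p,
       excluded = if (is.null(exclude)) character() else as.character(exclude))
}

#' Mean and standard deviation summary
#'
#' The `mean +/- sd` style summary. The sample convention (divide by n-1)
#' is the default; the population convention divides by n. For a single
#' value the sample sd is absent (`NA`).
#'
#' @param values numeric vector (non-empty).
#' @param convention `"sample"` or `"population"`.
#' @return list with `mean` and `sd`.
#' @export
mean_sd <- function(values, convention = c("sample", "population")) {
  convention <- match.arg(convention)
  if (length(values) == 0) stop("empty input", call. = FALSE)
  m <- mean(values)
  s <- if (convention == "sample") {
    if (length(values) < 2) NA_real_ else stats::sd(values)
  } else {
    sqrt(mean((values - m)^2))
  }
  list(mean = m, sd = s)
}

#' Rank labels by value, with tied groups
#'
#' Sorts labelled values and merges neighbours whose relative difference
#' `|a - b| / max(|a|, |b|)` is within `tie_tol` into tied groups (the
#' "~" of a printed ranking). Rate constants spanning orders of magnitude
#' need a generous tolerance to reproduce qualitative "~" groupings;
#' energies printed to 0.001 kcal/mol need a tight one.
#'
#' @param values named numeric vector.
#' @param direction `"ascending"` or `"descending"`.
#' @param tie_tol relative tolerance for declaring a tie (default 0.03).
#' @return list with `groups` (list of character vectors in rank order)
#'   and `ranking` (a display string using `<` or `>` and `~`).
#' @export
rank_order <- function(values, direction = c("ascending", "descending"),
                       tie_tol = 0.03) {
  direction <- match.arg(direction)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  ord <- order(values, decreasing = (direction == "descending"))
  v <- values[ord]
  labs <- names(v)
  groups <- list()
  cur <- labs[1]
  if (length(v) > 1) {
    for (i in 2:length(v)) {
      rel <- abs(v[i] - v[i - 1]) / max(abs(v[i]), abs(v[i - 1]), .Machine$double.eps)
      if (rel <= tie_tol) {
        cur <- c(cur, labs[i])
      } else {
        groups <- c(groups, list(cur))
        cur <- labs[i]
      }
    }
  }
  groups <- c(groups, list(cur))
  sep <- if (direction == "ascending") " < " else " > "
  ranking <- paste(vapply(groups, paste, character(1), collapse = " ~ "),
                   collapse = sep)
  list(groups = groups, ranking = ranking)
}

#' Recompute the derived cells of the reference tables
#'
#' Regenerates every derivable column of the packaged printed tables --
#' frontier-orbital gaps from HOMO/LUMO energies, thermal corrections as
#' BDE_COR - BDE, corrected barriers as dE_TS-R + dG_TS-R, reverse
#' barriers as dE_TS-R - dE_P-R, and rate constants from the printed
#' corrected barrier and imaginary frequency -- and reports every
#' printed-vs-recomputed discrepancy above tolerance. Discrepancies are
#' reported, never raised: a flagged row marks an internal inconsistency
#' of the printed table (one such row exists, see the package vignette).
#'
#' @param fixture a `study_tables` object from [study_tables()].
#' @param gap_tol absolute tolerance (kcal/mol) for sums of cells printed
#'   to 0.001 (default 0.0015, print-rounding).
#' @param rate_tol relative tolerance for recomputed rate constants
#'   (default 0.005; the printed values carry 4 significant digits).
#' @return list with `checks` (data frame of every recomputed cell) and
#'   `discrepancies` (the flagged subset).
#' @export
reproduce_tables <- function(fixture, gap_tol = 0.0015, rate_tol = 0.005) {
  checks <- list()
  add <- function(table, row, quantity, printed, recomputed, tol, relative) {
    dev <- if (relative) abs(recomputed - printed) / abs(printed)
           else abs(recomputed - printed)
    checks[[length(checks) + 1]] <<- data.frame(
      table = table, row = row, quantity = quantity,
      printed = printed, recomputed = recomputed,
      deviation = dev, flagged = dev > tol,
      stringsAsFactors = FALSE
    )
  }

  t1 <- fixture$table1
  for (i in seq_len(nrow(t1))) {
    for (lv in c("II", "III", "LC")) {
      eh <- t1[[paste0(lv, "_e_homo")]][i]
      el <- t1[[paste0(lv, "_e_lumo")]][i]
      gap <- t1[[paste0(lv, "_hl_gap")]][i]
      if (!is.na(eh) && !is.na(el) && !is.na(gap)) {
        add("table1", paste0(t1$compound[i], " (", lv, ")"), "hl_gap",
            gap, eh - el, gap_tol, relative = FALSE)
      }
    }
  }

  t2 <- fixture$table2
  for (i in seq_len(nrow(t2))) {
    for (ph in c("gas", "wat")) {
      eh <- t2[[paste0(ph, "_e_homo")]][i]
      el <- t2[[paste0(ph, "_e_lumo")]][i]
      gap <- t2[[paste0(ph, "_hl_gap")]][i]
      if (!is.na(eh) && !is.na(el) && !is.na(gap)) {
        add("table2", paste0(t2$compound[i], " (", ph, ")"), "hl_gap",
            gap, eh - el, gap_tol, relative = FALSE)
      }
    }
  }

  t3 <- fixture$table3
  for (i in seq_len(nrow(t3))) {
    row_id <- paste0(t3$compound[i], "--", t3$radical[i])
    # corrected barrier as the printed sum (level II)
    add("table3", row_id, "de_ts_r_cor",
        t3$de_ts_r_cor[i], t3$de_ts_r[i] + t3$dg_ts_r[i],
        gap_tol, relative = FALSE)
    # reverse barrier consistency: dE_TS-P = dE_TS-R - dE_P-R
    add("table3", row_id, "de_ts_p",
        t3$de_ts_p[i], t3$de_ts_r[i] - t3$de_p_r[i],
        gap_tol, relative = FALSE)
    # rate constants from printed corrected barrier + frequency
    add("table3", row_id, "k_II_gas",
        t3$k[i], rate_constant(t3$de_ts_r_cor[i], t3$nu_i[i])$rate,
        rate_tol, relative = TRUE)
    for (blk in c("g4", "w4")) {
      de <- t3[[paste0(blk, "_de_ts_r_cor")]][i]
      k <- t3[[paste0(blk, "_k")]][i]
      if (!is.na(de) && !is.na(k)) {
        add("table3", row_id, paste0("k_IV_", if (blk == "g4") "gas" else "water"),
            k, rate_constant(de, t3$nu_i[i])$rate, rate_tol, relative = TRUE)
      }
    }
  }

  checks <- do.call(rbind, checks)
  list(checks = checks,
       discrepancies = checks[checks$flagged, , drop = FALSE])
}
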