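#' Per-task condition cell means
#'
#' Computes, for one participant's classified trials, the mean RT (over
#' correct, in-bounds, non-excluded trials) and the error proportion (over
#' non-excluded trials) in each task x condition cell, together with the
#' trial counts. Condition means are then obtained by averaging across
#' tasks with equal weight per task (see [condition_means()]), which
#' protects against chance over-representation of the faster spatial
#' tasks in a condition.
#'
#' @param trials Classified trials of a single participant (see
#'   [classify_trials()]).
#' @param conditioning One of `"competitors"` (levels 0..3), `"bi"`
#'   (ABA/CBA) or `"crs"` (CRS+/CRS-, restricted to valid, interference-
#'   equated trials; see Details).
#' @details For the CRS conditioning, trials must first pass `crs_valid`
#'   and the two conditions are equated for the degree of interference:
#'   only trials in strata of (competitor count in N, competitor count in
#'   N-1) that are populated in both conditions for this participant are
#'   retained.
#' @return Data frame with columns `task`, `condition`, `mean_rt`, `n_rt`,
#'   `pe`, `n_pe`.
#' @export
per_task_condition_means <- function(trials,
                                     conditioning = c("competitors", "bi",
                                                      "crs")) {
  conditioning <- match.arg(conditioning)
  sel <- switch(conditioning,
    competitors = trials,
    bi = trials[trials$bi_label %in% c("ABA", "CBA"), , drop = FALSE],
    crs = equate_crs_strata(trials[trials$crs_valid, , drop = FALSE]))
  cond <- switch(conditioning,
    competitors = as.character(sel$n_competitors),
    bi = sel$bi_label,
    crs = sel$crs_label)
  levels_all <- switch(conditioning,
    competitors = as.character(0:3),
    bi = c("ABA", "CBA"),
    crs = c("CRSplus", "CRSminus"))

  grid <- expand.grid(task = TASKS, condition = levels_all,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- lapply(seq_len(nrow(grid)), function(i) {
    in_cell <- sel$task == grid$task[i] & cond == grid$condition[i]
    rt_tr <- sel$rt_ms[in_cell & sel$rt_included]
    pe_tr <- sel$correct[in_cell & sel$pe_included]
    data.frame(task = grid$task[i], condition = grid$condition[i],
               mean_rt = if (length(rt_tr)) mean(rt_tr) else NA_real_,
               n_rt = length(rt_tr),
               pe = if (length(pe_tr)) mean(!pe_tr) else NA_real_,
               n_pe = length(pe_tr), stringsAsFactors = FALSE)
  })
  do.call(rbind, cells)
}

# Restrict valid CRS trials to the interference-equated support. The two
# conditions structurally differ in previous-trial interference: a CRS+
# predecessor always holds at least one competitor (the now-relevant rule
# itself) while a CRS- predecessor holds at most two surviving ones, so
# trials are retained only on the shared support of one or two competitors
# in trial N-1. The interference distribution of trial N itself is
# identical across conditions by design and needs no restriction.
equate_crs_strata <- function(trials) {
  trials[!is.na(trials$n_competitors_prev) &
           trials$n_competitors_prev %in% 1:2, , drop = FALSE]
}

#' Equal-weight condition means across tasks
#'
#' Averages per-task cell means across tasks with equal task weights,
#' separately for RT and PE; a condition mean is missing if no task has
#' data in that condition.
#'
#' @param cells Output of [per_task_condition_means()].
#' @return Data frame with one row per condition: `condition`, `mean_rt`,
#'   `pe`, `n_rt`, `n_pe` (counts summed over tasks).
#' @export
condition_means <- function(cells) {
  conds <- unique(cells$condition)
  out <- lapply(conds, function(cn) {
    cc <- cells[cells$condition == cn, , drop = FALSE]
    data.frame(condition = cn,
               mean_rt = mean(cc$mean_rt[cc$n_rt > 0]),
               pe = mean(cc$pe[cc$n_pe > 0]),
               n_rt = sum(cc$n_rt), n_pe = sum(cc$n_pe),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Linear congruency index
#'
#' Contrast of the four competitor-level means with weights (-3, -1, 1, 3)
#' for 0, 1, 2 and 3 competitors; the sum of the products summarizes the
#' linear congruency trend in a single value per participant.
#'
#' @param means Numeric vector of the four condition means, ordered by
#'   competitor count 0..3.
#' @return The weighted sum, or `NA` if any level mean is missing.
#' @export
linear_congruency_index <- function(means) {
  if (length(means) != 4L) {
    stop("means must have four values (competitor levels 0..3)",
         call. = FALSE)
  }
  if (anyNA(means)) return(NA_real_)
  sum(c(-3, -1, 1, 3) * means)
}

#' Backward-inhibition index
#'
#' @param mean_aba,mean_cba Condition means for ABA and CBA trials.
#' @return `mean_aba - mean_cba`, or `NA` if either is missing.
#' @export
bi_index <- function(mean_aba, mean_cba) {
  if (is.na(mean_aba) || is.na(mean_cba)) return(NA_real_)
  mean_aba - mean_cba
}

#' Competitor-rule-suppression index
#'
#' @param mean_plus,mean_minus Condition means for CRS+ and CRS- trials.
#' @return `mean_plus - mean_minus`, or `NA` if either is missing.
#' @export
crs_index <- function(mean_plus, mean_minus) {
  if (is.na(mean_plus) || is.na(mean_minus)) return(NA_real_)
  mean_plus - mean_minus
}

#' Per-participant cognitive indices
#'
#' Computes the six indices (linear congruency, backward inhibition and
#' competitor rule suppression, each in RT and in PE) and overall RT/PE
#' for every participant in a classified trial table, along with the
#' minimum cell counts that feed the trial-count exclusion rules.
#'
#' @param trials Classified trial table (see [classify_trials()]).
#' @return Data frame with one row per participant: `participant`,
#'   `group`, the six index columns (`lin_cong_rt`, `lin_cong_pe`,
#'   `bi_rt`, `bi_pe`, `crs_rt`, `crs_pe`), `overall_rt`, `overall_pe`,
#'   `error_rate_all` (raw error rate over every trial), and the minimum
#'   per-condition (`min_cond_n`) and per-task-cell (`min_cell_n`) RT
#'   trial counts over all index conditions.
#' @export
compute_indices <- function(trials) {
  parts <- split(trials, trials$participant)
  out <- lapply(parts, function(tr) {
    cong_cells <- per_task_condition_means(tr, "competitors")
    bi_cells <- per_task_condition_means(tr, "bi")
    crs_cells <- per_task_condition_means(tr, "crs")
    cong <- condition_means(cong_cells)
    bi <- condition_means(bi_cells)
    crs <- condition_means(crs_cells)
    cong <- cong[match(as.character(0:3), cong$condition), ]
    aba <- bi[bi$condition == "ABA", ]; cba <- bi[bi$condition == "CBA", ]
    plus <- crs[crs$condition == "CRSplus", ]
    minus <- crs[crs$condition == "CRSminus", ]

    # CRS task cells are intrinsically sparse (~40 retained trials per
    # condition over four tasks), so the per-task-cell minimum is scoped
    # to the congruency and BI cells; CRS stability is protected by the
    # per-condition minimum instead.
    cells <- rbind(cong_cells, bi_cells)
    data.frame(
      participant = tr$participant[1], group = tr$group[1],
      lin_cong_rt = linear_congruency_index(cong$mean_rt),
      lin_cong_pe = linear_congruency_index(cong$pe),
      bi_rt = bi_index(aba$mean_rt, cba$mean_rt),
      bi_pe = bi_index(aba$pe, cba$pe),
      crs_rt = crs_index(plus$mean_rt, minus$mean_rt),
      crs_pe = crs_index(plus$pe, minus$pe),
      overall_rt = mean(tr$rt_ms[tr$rt_included]),
      overall_pe = mean(!tr$correct[tr$pe_included]),
      error_rate_all = mean(!tr$correct),
      min_cond_n = min(c(cong$n_rt, bi$n_rt, plus$n_rt, minus$n_rt)),
      min_cell_n = min(cells$n_rt),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out[unique(trials$participant)])
  rownames(res) <- NULL
  res
}

#' Robust MAD-based outlier mask
#'
#' Flags values deviating from the median by more than `k` scaled median
#' absolute deviations (consistency constant 1.4826, so the MAD estimates
#' the SD under normality).
#'
#' @param values Numeric vector (at least 3 values).
#' @param k Cut-off in MAD units (default 2.5).
#' @return Logical vector, `TRUE` for values to keep.
#' @export
mad_exclusion <- function(values, k = 2.5) {
  if (length(values) < 3L) {
    stop("mad_exclusion needs at least 3 values", call. = FALSE)
  }
  med <- stats::median(values)
  m <- stats::mad(values, center = med)  # 1.4826 consistency constant
  if (m == 0) {
    warning("MAD is zero; only exact-median values retained")
    return(values == med)
  }
  abs(values - med) <= k * m
}

#' Apply participant-level exclusions
#'
#' Applies, in order: (1) incomplete-data drop (missing RTs or short
#' sessions); (2) the overall error cap (computed on all trials before
#' anything else is removed); (3) MAD outlier exclusion on overall RT and
#' overall PE within each experimental group; (4) minimum-trial rules
#' (at least `min_per_condition` RT trials in every condition of every
#' index and at least `min_per_task_cell` in every task x condition cell);
#' (5) an optional offset-delay equipment filter.
#'
#' @param indices Per-participant indices from [compute_indices()].
#' @param expected_trials Trials a complete session must have (448).
#' @param n_trials Optional named vector of observed trial counts per
#'   participant (defaults to complete).
#' @param error_cap Maximum tolerated raw error rate (default 0.4).
#' @param mad_k MAD cut-off (default 2.5).
#' @param min_per_condition,min_per_task_cell Minimum RT trial counts
#'   (defaults 20 and 5).
#' @param offset Optional data frame with `participant`, `offset_mean`,
#'   `offset_sd` (ms) from the experiment platform.
#' @param offset_rule List with `mean` and `sd` thresholds (defaults 30
#'   and 36 ms) and `comparator`, `"above"` (default: exclude when the
#'   delay statistic exceeds its threshold) or `"below"`.
#' @return Object of class `participant_exclusions`: list with `report`
#'   (per-participant flags and reasons), `included` (ids), `indices`
#'   (filtered index table) and `group_counts`.
#' @export
apply_participant_exclusions <- function(indices, expected_trials = 448,
                                         n_trials = NULL, error_cap = 0.4,
                                         mad_k = 2.5,
                                         min_per_condition = 20,
                                         min_per_task_cell = 5,
                                         offset = NULL,
                                         offset_rule = list(
                                           mean = 30, sd = 36,
                                           comparator = "above")) {
  rep_df <- data.frame(participant = indices$participant,
                       group = indices$group, stringsAsFactors = FALSE)

  obs <- if (is.null(n_trials)) rep(expected_trials, nrow(indices))
         else unname(n_trials[as.character(indices$participant)])
  rep_df$incomplete_data <- obs < expected_trials |
    is.na(indices$overall_rt) | is.na(indices$overall_pe)

  rep_df$error_cap_over <- !rep_df$incomplete_data &
    indices$error_rate_all > error_cap

  pre_mad <- !rep_df$incomplete_data & !rep_df$error_cap_over
  rep_df$mad_rt <- rep_df$mad_pe <- FALSE
  for (g in unique(rep_df$group)) {
    in_g <- pre_mad & rep_df$group == g
    if (sum(in_g) >= 3) {
      rep_df$mad_rt[in_g] <- !mad_exclusion(indices$overall_rt[in_g], mad_k)
      rep_df$mad_pe[in_g] <- !mad_exclusion(indices$overall_pe[in_g], mad_k)
    }
  }

  rep_df$min_trials <- indices$min_cond_n < min_per_condition |
    indices$min_cell_n < min_per_task_cell |
    is.na(indices$lin_cong_rt) | is.na(indices$bi_rt) |
    is.na(indices$crs_rt)

  rep_df$offset_delay <- FALSE
  if (!is.null(offset)) {
    om <- offset$offset_mean[match(rep_df$participant, offset$participant)]
    os <- offset$offset_sd[match(rep_df$participant, offset$participant)]
    cmp <- match.arg(offset_rule$comparator, c("above", "below"))
    hit <- if (cmp == "above") om > offset_rule$mean | os > offset_rule$sd
           else                om < offset_rule$mean | os < offset_rule$sd
    rep_df$offset_delay <- !is.na(hit) & hit
  }

  flags <- c("incomplete_data", "error_cap_over", "mad_rt", "mad_pe",
             "min_trials", "offset_delay")
  rep_df$excluded <- Reduce(`|`, rep_df[flags])
  rep_df$reasons <- apply(rep_df[flags], 1, function(r) {
    paste(flags[r], collapse = ";")
  })

  kept <- indices[!rep_df$excluded, , drop = FALSE]
  if (!nrow(kept) || any(table(factor(kept$group,
                                      unique(rep_df$group))) == 0)) {
    stop("analysis aborted: a group is empty after exclusions",
         call. = FALSE)
  }
  counts <- aggregate(rep_df[flags], by = list(group = rep_df$group), sum)
  structure(list(report = rep_df,
                 included = rep_df$participant[!rep_df$excluded],
                 indices = kept, group_counts = counts),
            class = "participant_exclusions")
}

#' @export
print.participant_exclusions <- function(x, ...) {
  n <- nrow(x$report)
  cat(sprintf("Participant exclusions: %d of %d excluded, %d retained\n",
              sum(x$report$excluded), n, length(x$included)))
  print(x$group_counts, row.names = FALSE)
  invisible(x)
}

#' Cronbach's alpha
#'
#' @param items Numeric matrix or data frame, one column per item.
#' @return Alpha by the standard variance-ratio formula.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  if (k < 2) stop("alpha needs at least two items", call. = FALSE)
  v_items <- sum(apply(items, 2, stats::var))
  v_total <- stats::var(rowSums(items))
  k / (k - 1) * (1 - v_items / v_total)
}

#' Score the questionnaires
#'
#' Composites: the free-will inventory subscale score is the mean of its
#' five 1..7 items; subjective fatigue is the mean of the four items after
#' reverse-coding `alert` and `energetic` (8 - rating), so a high score
#' means more fatigue; locus of control is the number of internal choices
#' (0..23), high values meaning internal locus.
#'
#' @param q Questionnaire table from [simulate_group()] (items `fwi_1..5`,
#'   `fatigue_*`, `loc_1..23`, values within scale bounds).
#' @return Data frame of composites per participant with an `alphas`
#'   attribute giving Cronbach's alpha per scale (needs >= 2 respondents).
#' @export
score_questionnaires <- function(q) {
  fwi_items <- as.matrix(q[paste0("fwi_", 1:5)])
  fat_items <- cbind(q$fatigue_tired, q$fatigue_bored,
                     8 - q$fatigue_alert, 8 - q$fatigue_energetic)
  loc_items <- as.matrix(q[paste0("loc_", 1:23)])
  if (any(fwi_items < 1 | fwi_items > 7) ||
      any(q[c("fatigue_tired", "fatigue_bored", "fatigue_alert",
              "fatigue_energetic")] < 1) ||
      any(q[c("fatigue_tired", "fatigue_bored", "fatigue_alert",
              "fatigue_energetic")] > 7)) {
    stop("rating out of the 1..7 scale bounds", call. = FALSE)
  }
  if (!all(loc_items %in% c(0, 1))) {
    stop("locus-of-control items must be 0 (external) or 1 (internal)",
         call. = FALSE)
  }
  out <- data.frame(participant = q$participant, group = q$group,
                    fwi = rowMeans(fwi_items),
                    fatigue = rowMeans(fat_items),
                    loc = rowSums(loc_items), stringsAsFactors = FALSE)
  if (nrow(q) >= 2) {
    attr(out, "alphas") <- c(fwi = cronbach_alpha(fwi_items),
                             fatigue = cronbach_alpha(fat_items),
                             loc = cronbach_alpha(loc_items))
  }
  out
}
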