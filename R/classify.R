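#' Backward-inhibition sequence label for a task triplet
#'
#' In a 100%-switch sequence, trial N is an ABA trial when its task equals
#' the task of trial N-2 (the set abandoned on trial N-1 must be
#' re-engaged), and a CBA trial otherwise.
#'
#' @param task_n2,task_n1,task_n Tasks of three consecutive within-block
#'   trials.
#' @return `"ABA"` or `"CBA"`.
#' @export
classify_bi <- function(task_n2, task_n1, task_n) {
  if (identical(task_n, task_n1) || identical(task_n1, task_n2)) {
    stop("invalid sequence: consecutive trials share a task", call. = FALSE)
  }
  if (identical(task_n, task_n2)) "ABA" else "CBA"
}

#' Competitor-rule-suppression condition for a trial pair
#'
#' Trial N is only eligible under response alternation (the correct keys of
#' N-1 and N differ). It is a CRS+ trial when the now-relevant rule (the
#' feature of N's relevant dimension) was activated in trial N-1 as a
#' competitor, and a CRS- trial when that dimension's feature changed
#' between N-1 and N so the now-relevant rule was not activated in N-1
#' (with two response keys, response alternation then guarantees the
#' activated rule of that dimension was compatible in N-1, the
#' competitor-rule-priming control). The competitor-remains-competitor
#' flag marks trials in which some other dimension, irrelevant in N,
#' repeats a feature that competed in N-1.
#'
#' @param trial_n1,trial_n Lists or one-row data frames with `task` and the
#'   four feature entries, for consecutive within-block trials.
#' @param mapping A `response_mapping`.
#' @return List with `label` (`"CRSplus"`, `"CRSminus"` or
#'   `"ineligible"`), `response_alternation` and `crc` (logical
#'   competitor-remains-competitor flag).
#' @export
classify_crs <- function(trial_n1, trial_n, mapping) {
  get1 <- function(tr, f) {
    if (is.data.frame(tr)) tr[[f]][1] else tr[[f]]
  }
  task_n <- get1(trial_n, "task")
  task_n1 <- get1(trial_n1, "task")
  if (identical(task_n, task_n1)) {
    stop("invalid sequence: consecutive trials share a task", call. = FALSE)
  }
  stim_n <- vapply(TASKS, function(d) get1(trial_n, d), character(1))
  stim_n1 <- vapply(TASKS, function(d) get1(trial_n1, d), character(1))
  key_n <- correct_response(stim_n, task_n, mapping)
  key_n1 <- correct_response(stim_n1, task_n1, mapping)
  alternation <- key_n != key_n1

  repeat_rel <- stim_n[[task_n]] == stim_n1[[task_n]]
  label <- if (!alternation) {
    "ineligible"
  } else if (repeat_rel &&
             rule_key(mapping, task_n, stim_n1[[task_n]]) != key_n1) {
    "CRSplus"
  } else if (!repeat_rel &&
             rule_key(mapping, task_n, stim_n1[[task_n]]) == key_n1) {
    "CRSminus"
  } else {
    "ineligible"  # unreachable with binary keys, kept for safety
  }
  other <- setdiff(TASKS, task_n)
  crc <- any(vapply(other, function(d) {
    stim_n[[d]] == stim_n1[[d]] &&
      rule_key(mapping, d, stim_n1[[d]]) != key_n1
  }, logical(1)))
  list(label = label, response_alternation = alternation, crc = crc)
}

# Vectorised sequence classification for one participant's ordered trials.
# Uses only tasks, stimuli and the mapping (no responses), so it can run
# before RT/error generation. Returns a data frame of per-trial features.
classify_sequence <- function(trials, mapping) {
  n <- nrow(trials)
  stim_m <- as.matrix(trials[TASKS])
  task_idx <- match(trials$task, TASKS)
  if (anyNA(task_idx)) stop("unknown task dimension", call. = FALSE)

  key_m <- vapply(TASKS, function(d) rule_key(mapping, d, stim_m[, d]),
                  integer(n))
  if (n == 1L) key_m <- matrix(key_m, nrow = 1, dimnames = list(NULL, TASKS))
  correct_key <- key_m[cbind(seq_len(n), task_idx)]
  n_competitors <- as.integer(rowSums(key_m != correct_key))

  # same-block adjacency of the rows actually present (robust to partial
  # blocks): sb1 marks rows whose predecessor row is the preceding trial
  # of the same block, sb2 rows with two such predecessors
  lag1 <- function(x, fill) c(fill, x[-n])
  lag2 <- function(x, fill) if (n > 2L) c(fill, fill, x[-c(n - 1L, n)])
                            else rep(fill, n)
  sb1 <- seq_len(n) > 1L & trials$block == lag1(trials$block, -1L)
  sb2 <- sb1 & lag1(sb1, FALSE)
  if (any(sb1 & trials$task == lag1(trials$task, ""))) {
    stop("invalid sequence: consecutive trials share a task", call. = FALSE)
  }

  # ABA/CBA needs two same-block predecessors
  bi_label <- rep("unclassified", n)
  bi_label[sb2] <- ifelse(trials$task[sb2] == lag2(trials$task, "")[sb2],
                          "ABA", "CBA")

  prev_key <- lag1(correct_key, NA_integer_)
  alternation <- sb1 & correct_key != prev_key

  # feature of N's relevant dimension on trial N-1
  stim_prev <- rbind(rep(NA_character_, 4), stim_m[-n, , drop = FALSE])
  feat_rel_n <- stim_m[cbind(seq_len(n), task_idx)]
  feat_rel_prev <- stim_prev[cbind(seq_len(n), task_idx)]
  repeat_rel <- sb1 & feat_rel_n == feat_rel_prev

  crs_label <- rep("ineligible", n)
  crs_label[alternation & repeat_rel] <- "CRSplus"
  crs_label[alternation & !repeat_rel] <- "CRSminus"

  # competitor-remains-competitor: a dimension irrelevant in N repeats a
  # feature that was a competitor rule in N-1
  comp_m <- key_m != correct_key            # competitor indicator per trial
  comp_prev <- rbind(rep(NA, 4), comp_m[-n, , drop = FALSE])
  rep_m <- stim_m == stim_prev
  crc_m <- rep_m & comp_prev
  crc_m[cbind(seq_len(n), task_idx)] <- FALSE
  crc <- sb1 & rowSums(crc_m, na.rm = TRUE) > 0

  data.frame(correct_key = correct_key, n_competitors = n_competitors,
             bi_label = bi_label, crs_label = crs_label,
             response_alternation = alternation, crs_crc = crc,
             n_competitors_prev = ifelse(sb1, lag1(n_competitors,
                                                   NA_integer_),
                                         NA_integer_),
             stringsAsFactors = FALSE)
}

#' Classify and flag a long-format trial table
#'
#' Annotates every trial with its competitor count, backward-inhibition
#' label, CRS condition and the trial-level exclusion flags:
#' \itemize{
#'   \item `excl_first_four`: the first four trials of each block;
#'   \item `excl_post_error`: the two trials following an error (within
#'     block);
#'   \item `excl_full_repetition`: the stimulus repeats the previous
#'     trial's stimulus on all four dimensions (feature-binding control);
#'   \item `excl_rt_bounds`: RT below 100 ms or above 3000 ms (RT analyses
#'     only).
#' }
#' Derived inclusion columns: `rt_included` (correct, in-bounds,
#' non-excluded; the basis of RT cell means), `pe_included` (non-excluded
#' regardless of correctness; the basis of error proportions) and
#' `crs_valid` (CRS-labelled trials passing the
#' competitor-remains-competitor control whose predecessor is itself a
#' clean trial).
#'
#' @param trials Long trial table as produced by [simulate_participant()]
#'   or [simulate_group()], ordered by participant, block, trial.
#' @param mapping Optional `response_mapping` used for every participant;
#'   by default each participant's `mapping` column selects one of the
#'   eight standard mappings.
#' @return The input table with classification and flag columns appended.
#' @export
classify_trials <- function(trials, mapping = NULL) {
  req <- c("participant", "block", "trial", "task", TASKS,
           "correct", "rt_ms")
  miss <- setdiff(req, names(trials))
  if (length(miss)) {
    stop("trials table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  # drop any stale classification columns so the operation is idempotent
  keep <- setdiff(names(trials), c(
    "correct_key", "n_competitors", "bi_label", "crs_label",
    "response_alternation", "crs_crc", "n_competitors_prev",
    "excl_first_four", "excl_post_error", "excl_full_repetition",
    "excl_rt_bounds", "excluded", "rt_included", "pe_included",
    "crs_valid"))
  trials <- trials[keep]

  parts <- split(seq_len(nrow(trials)), trials$participant)
  out <- lapply(parts, function(idx) {
    tr <- trials[idx, , drop = FALSE]
    ord <- order(tr$block, tr$trial)
    if (!identical(ord, seq_len(nrow(tr)))) {
      stop("ordering error: trials must be sorted by block and trial",
           call. = FALSE)
    }
    m <- mapping
    if (is.null(m)) {
      if (!"mapping" %in% names(tr)) {
        stop("no mapping column and no mapping argument", call. = FALSE)
      }
      m <- response_mapping(tr$mapping[1])
    }
    cls <- classify_sequence(tr, m)
    tr$correct_key <- cls$correct_key
    tr <- cbind(tr, cls[setdiff(names(cls), "correct_key")])

    n <- nrow(tr)
    sb1 <- seq_len(n) > 1L & tr$block == c(-1L, tr$block[-n])
    sb2 <- sb1 & c(FALSE, sb1[-n])
    tr$excl_first_four <- tr$trial <= 4L
    err <- !tr$correct
    post1 <- c(FALSE, err[-n]) & sb1
    post2 <- if (n > 2L) c(FALSE, FALSE, err[-c(n - 1L, n)]) & sb2
             else rep(FALSE, n)
    tr$excl_post_error <- post1 | post2
    stim_m <- as.matrix(tr[TASKS])
    full_rep <- c(FALSE, rowSums(stim_m[-1L, , drop = FALSE] ==
                                   stim_m[-n, , drop = FALSE]) == 4L)
    tr$excl_full_repetition <- full_rep & sb1
    tr$excl_rt_bounds <- tr$rt_ms < 100 | tr$rt_ms > 3000

    tr$excluded <- tr$excl_first_four | tr$excl_post_error |
      tr$excl_full_repetition
    tr$rt_included <- !tr$excluded & tr$correct & !tr$excl_rt_bounds
    tr$pe_included <- !tr$excluded

    prev_clean <- c(FALSE, (!tr$excl_first_four & !tr$excl_post_error &
                              tr$correct)[-n]) & sb1
    tr$crs_valid <- tr$crs_label %in% c("CRSplus", "CRSminus") &
      !tr$crs_crc & !tr$excluded & prev_clean
    tr
  })
  res <- do.call(rbind, out[unique(trials$participant)])
  rownames(res) <- NULL
  res
}
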