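#' Write / read a long-format trial table
#'
#' Plain CSV with one row per trial (participant, group, mapping, block,
#' trial, task, the four stimulus feature columns, correct_key,
#' response_key, correct, rt_ms, plus any classification columns present).
#'
#' @param trials Trial table.
#' @param path File path.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
}

#' @rdname write_trial_table
#' @return `read_trial_table` returns the trial data frame with logical
#'   columns restored.
#' @export
read_trial_table <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cl in intersect(c("correct", "response_alternation", "crs_crc",
                         "excl_first_four", "excl_post_error",
                         "excl_full_repetition", "excl_rt_bounds",
                         "excluded", "rt_included", "pe_included",
                         "crs_valid"), names(tr))) {
    tr[[cl]] <- as.logical(tr[[cl]])
  }
  tr
}

#' Write / read a questionnaire table
#' @param q Questionnaire item table from [simulate_group()].
#' @param path File path.
#' @export
write_questionnaire_table <- function(q, path) {
  utils::write.csv(q, path, row.names = FALSE)
}

#' @rdname write_questionnaire_table
#' @export
read_questionnaire_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read generator parameters from a YAML or JSON config file
#'
#' The file holds any subset of the [gen_params()] arguments (nested
#' `group_d` and `index_sd` as named maps); unspecified entries keep
#' their defaults.
#'
#' @param path Path to a YAML (or JSON, which YAML subsumes) file.
#' @return A `gen_params` object.
#' @export
read_sim_config <- function(path) {
  conf <- yaml::read_yaml(path)
  known <- names(formals(gen_params))
  unknown <- setdiff(names(conf), known)
  if (length(unknown)) {
    stop("unknown config entries: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in c("group_d", "index_sd")) {
    if (!is.null(conf[[nm]])) conf[[nm]] <- unlist(conf[[nm]])
  }
  do.call(gen_params, conf)
}
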