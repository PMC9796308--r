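#' @keywords internal
"_PACKAGE"

# The four classification dimensions and their binary feature values.
# Spatial tasks (vertical/horizontal position) are treated separately from
# object tasks (colour/shape) because they are typically faster.
TASKS <- c("colour", "shape", "vertical", "horizontal")
SPATIAL_TASKS <- c("vertical", "horizontal")
FEATURES <- list(
  colour     = c("green", "red"),
  shape      = c("circle", "triangle"),
  vertical   = c("up", "down"),
  horizontal = c("left", "right")
)

#' Task dimensions of the switching paradigm
#'
#' @return Character vector of the four task names: classification by
#'   colour, shape, vertical position and horizontal position.
#' @export
task_dimensions <- function() TASKS

#' Enumerate the 16 stimuli
#'
#' Every stimulus is a combination of one feature per dimension (a red or
#' green, circle or triangle, in one of the four grid quadrants), giving
#' 2^4 = 16 distinct stimuli.
#'
#' @return A data frame with 16 rows and columns `colour`, `shape`,
#'   `vertical`, `horizontal`.
#' @export
stimulus_set <- function() {
  s <- expand.grid(FEATURES[TASKS], KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  s[, TASKS]
}

#' Construct one of the eight counterbalanced response mappings
#'
#' All four tasks share the same two abstract response keys (`key1`,
#' `key2`). The two spatial tasks are yoked to the physical key arrangement
#' (up/left vs. up/right on the same key), and the key assignment of the
#' colour and the shape task is counterbalanced independently, giving
#' 2 x 2 x 2 = 8 mapping conditions.
#'
#' @param mapping_id Integer in 1..8.
#' @return An object of class `response_mapping`: a list with `id` and
#'   `rule`, a named integer vector mapping `"dimension:feature"` to key
#'   1 or 2.
#' @examples
#' m <- response_mapping(1)
#' m$rule[["colour:green"]]
#' @export
response_mapping <- function(mapping_id) {
  if (length(mapping_id) != 1L || is.na(mapping_id) ||
      mapping_id != as.integer(mapping_id) ||
      mapping_id < 1 || mapping_id > 8) {
    stop("mapping_id must be a single integer in 1..8", call. = FALSE)
  }
  mapping_id <- as.integer(mapping_id)
  bits <- as.integer(intToBits(mapping_id - 1L))[1:3]  # spatial, colour, shape

  rule <- integer(0)
  if (bits[1] == 0L) {
    # up and left share key 1 (E/N arrangement)
    spat <- c("vertical:up" = 1L, "vertical:down" = 2L,
              "horizontal:left" = 1L, "horizontal:right" = 2L)
  } else {
    # up and right share key 1 (U/C arrangement)
    spat <- c("vertical:up" = 1L, "vertical:down" = 2L,
              "horizontal:right" = 1L, "horizontal:left" = 2L)
  }
  col <- if (bits[2] == 0L) c("colour:green" = 1L, "colour:red" = 2L)
         else               c("colour:red" = 1L, "colour:green" = 2L)
  shp <- if (bits[3] == 0L) c("shape:circle" = 1L, "shape:triangle" = 2L)
         else               c("shape:triangle" = 1L, "shape:circle" = 2L)
  rule <- c(col, shp, spat)

  structure(list(id = mapping_id, rule = rule), class = "response_mapping")
}

#' All eight response mappings
#' @return A list of eight `response_mapping` objects.
#' @export
all_response_mappings <- function() lapply(1:8, response_mapping)

#' @export
print.response_mapping <- function(x, ...) {
  cat("Response mapping", x$id, "\n")
  for (d in TASKS) {
    f <- FEATURES[[d]]
    cat(sprintf("  %-10s %s -> key%d, %s -> key%d\n", d,
                f[1], x$rule[[paste0(d, ":", f[1])]],
                f[2], x$rule[[paste0(d, ":", f[2])]]))
  }
  invisible(x)
}

as_stimulus <- function(stimulus) {
  if (is.data.frame(stimulus)) stimulus <- unlist(stimulus[1, TASKS])
  stim <- unlist(stimulus)
  if (!all(TASKS %in% names(stim))) {
    stop("stimulus must have named features for all four dimensions",
         call. = FALSE)
  }
  stim[TASKS]
}

#' Correct response key for a stimulus under a task
#'
#' Looks up the stimulus-response rule of the currently relevant dimension.
#'
#' @param stimulus Named character vector (or one-row data frame) with
#'   entries `colour`, `shape`, `vertical`, `horizontal`.
#' @param task One of `"colour"`, `"shape"`, `"vertical"`, `"horizontal"`.
#' @param mapping A `response_mapping`.
#' @return Integer key, 1 or 2.
#' @export
correct_response <- function(stimulus, task, mapping) {
  if (!inherits(mapping, "response_mapping")) {
    stop("mapping must be a response_mapping", call. = FALSE)
  }
  if (length(task) != 1L || !task %in% TASKS) {
    stop("unknown task dimension: ", paste(task, collapse = ", "),
         call. = FALSE)
  }
  stim <- as_stimulus(stimulus)
  unname(mapping$rule[[paste0(task, ":", stim[[task]])]])
}

# Vectorised key lookup: feature values of dimension `dim` for many trials.
rule_key <- function(mapping, dim, features) {
  unname(mapping$rule[paste0(dim, ":", features)])
}

#' Number of competitor S-R sets on a trial
#'
#' A competitor set is an irrelevant dimension whose activated rule (the
#' rule matching the stimulus' feature on that dimension) maps to the key
#' that differs from the correct response. With three irrelevant
#' dimensions the count ranges over 0..3.
#'
#' @inheritParams correct_response
#' @return Integer in 0..3.
#' @export
count_competitors <- function(stimulus, task, mapping) {
  stim <- as_stimulus(stimulus)
  key <- correct_response(stim, task, mapping)
  irrelevant <- setdiff(TASKS, task)
  sum(vapply(irrelevant, function(d) {
    rule_key(mapping, d, stim[[d]]) != key
  }, logical(1)))
}

#' Generate a 100%-switch task sequence
#'
#' Tasks are ordered randomly under the constraint that every trial is a
#' task switch: the task of trial N is drawn uniformly among the
#' `n_tasks - 1` tasks other than the task of trial N-1. The constraint is
#' applied across the whole session (so it also holds within every block).
#'
#' @param n_blocks Number of blocks (default 7).
#' @param trials_per_block Trials per block (default 64).
#' @param n_tasks Number of tasks, 2..4 (default 4).
#' @param seed Optional integer seed; the global RNG state is restored on
#'   exit.
#' @return Character vector of task names of length
#'   `n_blocks * trials_per_block`.
#' @export
generate_task_sequence <- function(n_blocks = 7, trials_per_block = 64,
                                   n_tasks = 4, seed = NULL) {
  if (n_tasks < 2) stop("invalid design: n_tasks must be >= 2", call. = FALSE)
  if (n_tasks > length(TASKS)) {
    stop("invalid design: at most ", length(TASKS), " tasks", call. = FALSE)
  }
  if (n_blocks < 1 || trials_per_block < 1) {
    stop("invalid design: n_blocks and trials_per_block must be >= 1",
         call. = FALSE)
  }
  tasks <- TASKS[seq_len(n_tasks)]
  n <- n_blocks * trials_per_block
  with_seed(seed, {
    out <- character(n)
    out[1] <- sample(tasks, 1L)
    for (i in seq_len(n - 1L)) {
      candidates <- tasks[tasks != out[i]]
      out[i + 1L] <- if (length(candidates) == 1L) candidates
                     else sample(candidates, 1L)
    }
    out
  })
}
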