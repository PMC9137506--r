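#' Go/NoGo task configuration
#'
#' Describes an event-related Go/NoGo run in which every EPI volume
#' acquisition triggers one trial: frequent Go stimuli requiring a button
#' press and rare NoGo stimuli requiring response inhibition. Defaults
#' match a 200-volume run at TR 2 s with 80/20 Go/NoGo proportions and a
#' 500 ms stimulus.
#'
#' @param n_trials Number of trials (= number of volumes in the run).
#' @param nogo_fraction Proportion of NoGo trials, in \[0, 1\].
#' @param tr_seconds Repetition time in seconds (one trial per TR).
#' @param stimulus_ms Stimulus duration in milliseconds (metadata only;
#'   regressors are sampled at TR resolution).
#' @param seed Optional integer seed making sequence generation
#'   reproducible.
#' @return An object of class `task_config`.
#' @seealso [generate_task_sequence()], [simulate_performance()]
#' @export
task_config <- function(n_trials = 200L, nogo_fraction = 0.2,
                        tr_seconds = 2, stimulus_ms = 500, seed = NULL) {
  check_number(n_trials, "n_trials", min = 1)
  check_number(nogo_fraction, "nogo_fraction", min = 0, max = 1)
  check_number(tr_seconds, "tr_seconds", min = .Machine$double.eps)
  check_number(stimulus_ms, "stimulus_ms", min = 0)
  structure(list(n_trials = as.integer(n_trials),
                 nogo_fraction = nogo_fraction,
                 tr_seconds = tr_seconds,
                 stimulus_ms = stimulus_ms,
                 seed = seed),
            class = "task_config")
}

#' Generate a randomly interspersed Go/NoGo trial sequence
#'
#' Places exactly `round(n_trials * nogo_fraction)` NoGo trials at positions
#' drawn uniformly at random without constraint; all remaining trials are Go.
#'
#' @param cfg A [task_config()].
#' @return Character vector of length `n_trials` with values `"go"` or
#'   `"nogo"`.
#' @examples
#' seq <- generate_task_sequence(task_config(seed = 1))
#' table(seq)  # 160 go, 40 nogo
#' @export
generate_task_sequence <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  n <- cfg$n_trials
  n_nogo <- round(n * cfg$nogo_fraction)
  seqc <- rep("go", n)
  if (n_nogo > 0) {
    pos <- with_seed(cfg$seed, sample.int(n, n_nogo))
    seqc[pos] <- "nogo"
  }
  seqc
}

outcome_levels <- c("correct_go", "correct_nogo", "omission", "commission")

#' Simulate trial outcomes as a one-hot performance matrix
#'
#' Each Go trial becomes a correct Go with probability `go_accuracy` and an
#' omission error otherwise; each NoGo trial becomes a correct NoGo with
#' probability `nogo_accuracy` and a commission error otherwise. The four
#' outcomes are mutually exclusive, so every row of the returned matrix Z
#' has exactly one nonzero entry.
#'
#' @param sequence Character vector of `"go"`/`"nogo"` trial labels.
#' @param go_accuracy,nogo_accuracy Probabilities of a correct response,
#'   in \[0, 1\].
#' @param seed Optional integer seed.
#' @return An `n x 4` binary matrix of class `performance_matrix` with
#'   columns `correct_go`, `correct_nogo`, `omission`, `commission`.
#' @export
simulate_performance <- function(sequence, go_accuracy = 0.9,
                                 nogo_accuracy = 0.85, seed = NULL) {
  if (length(sequence) == 0L) stop_bad("`sequence` must be non-empty")
  if (!all(sequence %in% c("go", "nogo")))
    stop_bad("`sequence` entries must be \"go\" or \"nogo\"")
  check_number(go_accuracy, "go_accuracy", 0, 1)
  check_number(nogo_accuracy, "nogo_accuracy", 0, 1)
  n <- length(sequence)
  is_go <- sequence == "go"
  correct <- with_seed(seed, {
    u <- stats::runif(n)
    ifelse(is_go, u < go_accuracy, u < nogo_accuracy)
  })
  col <- ifelse(is_go,
                ifelse(correct, 1L, 3L),   # correct go / omission
                ifelse(correct, 2L, 4L))   # correct nogo / commission
  Z <- matrix(0L, n, 4L, dimnames = list(NULL, outcome_levels))
  Z[cbind(seq_len(n), col)] <- 1L
  class(Z) <- c("performance_matrix", class(Z))
  Z
}

#' Validate a performance matrix
#'
#' Checks the one-hot invariant: binary entries and unit row sums.
#'
#' @param Z A matrix to validate.
#' @return `Z`, invisibly, with class `performance_matrix`.
#' @export
as_performance_matrix <- function(Z) {
  Z <- as.matrix(Z)
  if (ncol(Z) != 4L) stop_bad("performance matrix must have 4 columns")
  if (!all(Z %in% c(0, 1))) stop_bad("performance matrix must be binary")
  if (!all(rowSums(Z) == 1))
    stop_bad("each performance-matrix row must have exactly one 1")
  storage.mode(Z) <- "integer"
  colnames(Z) <- outcome_levels
  if (!inherits(Z, "performance_matrix"))
    class(Z) <- c("performance_matrix", class(Z))
  invisible(Z)
}
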