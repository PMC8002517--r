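#' Openness simulation configuration
#'
#' Parameters of the gradual-enrollment simulation: the number of enrolled
#' subjects grows from `t1` to `tr` over `steps` steps, with per-step
#' increments drawn from a binomial step law, and `sequences` independent
#' nested label sequences are generated over the `n_subjects` available
#' labels. The last-step size must satisfy `tr < n_subjects` so that label
#' sequences are drawn from a large combination space.
#'
#' @param t1 Number of subjects at the first step (>= 1).
#' @param tr Number of subjects at the last step (`t1 <= tr < n_subjects`).
#' @param steps Number of steps R (>= 1).
#' @param n_subjects Total number of available subject labels E.
#' @param step_trials Binomial trial count of the step law.
#' @param step_prob Binomial success probability of the step law.
#' @param sequences Number of independent label sequences M (>= 1).
#' @param seed Master seed; sizes and each label sequence use independent
#'   sub-streams, so increasing `sequences` never perturbs earlier sequences.
#' @return An object of class `openness_config`.
#' @export
#' @examples
#' openness_config(t1 = 5, tr = 97, steps = 24, n_subjects = 108)
openness_config <- function(t1, tr, steps, n_subjects,
                            step_trials = 100L, step_prob = 0.04,
                            sequences = 10L, seed = 1L) {
  t1 <- check_number(t1, "t1", lower = 1, integer = TRUE)
  tr <- check_number(tr, "tr", lower = t1, integer = TRUE)
  n_subjects <- check_number(n_subjects, "n_subjects", lower = 2, integer = TRUE)
  if (tr >= n_subjects)
    stop_field("tr", sprintf("must be below n_subjects (%d): the last step keeps the system open", n_subjects))
  steps <- check_number(steps, "steps", lower = 1, integer = TRUE)
  step_trials <- check_number(step_trials, "step_trials", lower = 1, integer = TRUE)
  step_prob <- check_number(step_prob, "step_prob", lower = 0, upper = 1, strict_lower = TRUE)
  sequences <- check_number(sequences, "sequences", lower = 1, integer = TRUE)
  seed <- check_number(seed, "seed", integer = TRUE)
  if (steps - 1L > tr - t1)
    stop_field("steps", sprintf("infeasible: %d steps need at least %d new subjects but tr - t1 = %d",
                                steps, steps - 1L, tr - t1))
  if (steps == 1L && t1 != tr)
    stop_field("steps", "steps = 1 requires t1 == tr")
  structure(list(t1 = t1, tr = tr, steps = steps, n_subjects = n_subjects,
                 step_trials = step_trials, step_prob = step_prob,
                 sequences = sequences, seed = seed),
            class = "openness_config")
}

#' Simulate the size sequence of the openness condition
#'
#' Draws the `steps - 1` per-step enrollment increments from
#' `Binomial(step_trials, step_prob)`, redrawing zeros (every step must
#' enroll at least one novel subject), and rejection-samples whole increment
#' vectors until they sum exactly to `tr - t1`. Cumulative sums give the
#' strictly increasing size sequence `T` with `T[1] = t1` and
#' `T[steps] = tr`.
#'
#' @param cfg An [openness_config()].
#' @param max_attempts Rejection-sampling budget.
#' @return Integer vector of length `steps`.
#' @export
simulate_sizes <- function(cfg, max_attempts = 100000L) {
  stopifnot(inherits(cfg, "openness_config"))
  if (cfg$steps == 1L) return(cfg$t1)
  target <- cfg$tr - cfg$t1
  k <- cfg$steps - 1L
  inc <- with_seed(sub_seed(cfg$seed, 0L), {
    found <- NULL
    for (attempt in seq_len(max_attempts)) {
      draw <- stats::rbinom(k, cfg$step_trials, cfg$step_prob)
      while (any(draw == 0L))
        draw[draw == 0L] <- stats::rbinom(sum(draw == 0L), cfg$step_trials, cfg$step_prob)
      if (sum(draw) == target) { found <- draw; break }
    }
    if (is.null(found))
      stop(sprintf(paste0("could not draw a size sequence summing to %d in %d attempts; ",
                          "check that the step law is compatible with (t1, tr, steps)"),
                   target, max_attempts), call. = FALSE)
    found
  })
  as.integer(cfg$t1 + c(0L, cumsum(inc)))
}

#' Simulate nested label sequences
#'
#' For each of the `sequences` independent sequences: starting from the full
#' pool of unknown labels `1..n_subjects`, at every step draw
#' `T[n] - T[n-1]` labels uniformly at random without replacement from the
#' pool, add them to the enrolled set and remove them from the pool. The
#' step-`n` label sets are therefore nested and of size `T[n]`.
#'
#' @param cfg An [openness_config()].
#' @param sizes Size sequence from [simulate_sizes()] (computed if omitted).
#' @return List of `sequences` lists, each containing `steps` integer label
#'   vectors.
#' @export
simulate_labels <- function(cfg, sizes = simulate_sizes(cfg)) {
  stopifnot(inherits(cfg, "openness_config"))
  sizes <- as.integer(sizes)
  if (length(sizes) != cfg$steps || sizes[1] != cfg$t1 ||
      sizes[length(sizes)] != cfg$tr || (length(sizes) > 1 && any(diff(sizes) <= 0)))
    stop("invalid size sequence for this configuration", call. = FALSE)
  lapply(seq_len(cfg$sequences), function(i) {
    with_seed(sub_seed(cfg$seed, i), {
      unknown <- seq_len(cfg$n_subjects)
      enrolled <- integer(0)
      prev <- 0L
      steps <- vector("list", cfg$steps)
      for (n in seq_len(cfg$steps)) {
        add <- sample(unknown, sizes[n] - prev)
        enrolled <- c(enrolled, add)
        unknown <- setdiff(unknown, add)
        prev <- sizes[n]
        steps[[n]] <- sort(enrolled)
      }
      steps
    })
  })
}

#' Run the full openness simulation
#'
#' Combines [simulate_sizes()] and [simulate_labels()] into one replayable
#' object `S = (T, L)`.
#'
#' @param cfg An [openness_config()].
#' @return An object of class `openness_sim`: list with `sizes`, `sequences`
#'   and `config`.
#' @export
simulate_openness <- function(cfg) {
  sizes <- simulate_sizes(cfg)
  structure(list(sizes = sizes,
                 sequences = simulate_labels(cfg, sizes),
                 config = cfg),
            class = "openness_sim")
}

#' @export
print.openness_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Openness simulation: %d -> %d subjects over %d steps, %d sequence(s) (E = %d)\n",
              cfg$t1, cfg$tr, cfg$steps, cfg$sequences, cfg$n_subjects))
  cat("  sizes:", paste(x$sizes, collapse = " "), "\n")
  invisible(x)
}

#' Write an openness simulation to JSON
#'
#' Captures the configuration, the size sequence and all label sequences so
#' that an evaluation can be replayed bit-exactly.
#'
#' @param sim An [simulate_openness()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_openness <- function(sim, path) {
  stopifnot(inherits(sim, "openness_sim"))
  jsonlite::write_json(list(config = unclass(sim$config),
                            sizes = sim$sizes,
                            sequences = sim$sequences),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an openness simulation written by [write_openness()]
#'
#' @param path JSON path.
#' @return An `openness_sim` object.
#' @export
read_openness <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(openness_config, raw$config)
  seqs <- lapply(raw$sequences, function(s) lapply(s, as.integer))
  structure(list(sizes = as.integer(raw$sizes), sequences = seqs, config = cfg),
            class = "openness_sim")
}
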