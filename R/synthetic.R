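#' The 25-node scale-free stimulus network
#'
#' Grows the stimulus shown to participants: a Barabasi-Albert
#' scale-free network built by the probability-matching growth process
#' with L = 1 and m = 3, 25 nodes (69 edges, minimum degree 3).
#'
#' @param seed integer seed; the same seed reproduces the identical
#'   edge set.
#' @return an `igraph` graph.
#' @export
make_stimulus <- function(seed = 1L) {
  grow_network(25L, m = 3L, policy = attachment_policy("fixed", L = 1),
               seed = seed)
}

#' Configuration of a synthetic behavioral cohort
#'
#' Defaults mirror the reference study: 600 participants whose true
#' sensitivities are Gaussian with mean 0.68 and s.d. 3.1 (truncated at
#' plus or minus 10), choices generated by the softmax rule on a 25-node
#' stimulus, and an extraversion score constructed to correlate 0.17
#' with the true L. Trait scores live on the 1-5 BFI-10 scale.
#'
#' @param n_participants cohort size.
#' @param L_mean,L_sd population mean and sd of the true L.
#' @param L_lo,L_hi truncation bounds of the generative L distribution.
#' @param extraversion_target_r target population correlation between
#'   extraversion and the true L (|r| < 1).
#' @param trait_min,trait_max trait score range.
#' @param round_traits round trait scores to the half-point BFI-10 grid
#'   (off by default; no downstream computation depends on it).
#' @param stimulus_seed,cohort_seed the two seeds all randomness flows
#'   from.
#' @return an object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_participants = 600L, L_mean = 0.68, L_sd = 3.1,
                          L_lo = -10, L_hi = 10,
                          extraversion_target_r = 0.17,
                          trait_min = 1, trait_max = 5,
                          round_traits = FALSE,
                          stimulus_seed = 1L, cohort_seed = 1L) {
  stopifnot(n_participants >= 1, L_sd >= 0, L_lo < L_hi,
            abs(extraversion_target_r) < 1, trait_min < trait_max)
  structure(as.list(environment()), class = "cohort_config")
}

# map a standardized score onto the trait scale: center 3, slope 0.75
# puts +/- 2.7 sd inside [1, 5]; clipping is rare and mild
trait_scale <- function(z, config) {
  mid <- (config$trait_min + config$trait_max) / 2
  span <- (config$trait_max - config$trait_min) / 2
  x <- mid + 0.375 * span * z
  x <- pmin(pmax(x, config$trait_min), config$trait_max)
  if (config$round_traits) x <- round(x * 2) / 2
  x
}

#' Generate a synthetic behavioral cohort
#'
#' The generative twin of the individual-differences model: true
#' sensitivities L_i are drawn from the truncated Gaussian of the
#' config; each participant makes a first selection from all stimulus
#' nodes by the softmax rule at L_i and a second from the remaining
#' nodes (first choice excluded); extraversion is built from the
#' standardized true L plus independent Gaussian noise to hit the
#' target population correlation, and the other four traits are
#' independent of L. All randomness flows from `stimulus_seed` and
#' `cohort_seed`.
#'
#' @param config a [cohort_config()].
#' @return a `synthetic_cohort`: `stimulus` (igraph), `records` (choice
#'   table), `personality` (trait table), `true_L` (ground truth, kept
#'   out of pipeline inputs), `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  stimulus <- make_stimulus(config$stimulus_seed)
  deg <- igraph::degree(stimulus)
  n_nodes <- length(deg)
  P <- config$n_participants

  set.seed(config$cohort_seed)
  true_L <- rtruncnorm(P, config$L_mean, config$L_sd, config$L_lo, config$L_hi)

  first <- integer(P)
  second <- integer(P)
  for (i in seq_len(P)) {
    p1 <- choice_probabilities(deg, true_L[i])
    first[i] <- sample.int(n_nodes, 1L, prob = p1)
    p2 <- choice_probabilities(deg, true_L[i], excluded = first[i])
    second[i] <- sample.int(n_nodes, 1L, prob = p2)
  }
  records <- data.frame(participant_id = seq_len(P),
                        first_choice = first - 1L,
                        second_choice = second - 1L)

  z_L <- if (stats::sd(true_L) > 0) {
    (true_L - mean(true_L)) / stats::sd(true_L)
  } else {
    rep(0, P)
  }
  r <- config$extraversion_target_r
  extraversion <- trait_scale(r * z_L + sqrt(1 - r^2) * stats::rnorm(P), config)
  other <- replicate(4, trait_scale(stats::rnorm(P), config))
  personality <- data.frame(participant_id = seq_len(P),
                            openness = other[, 1L],
                            conscientiousness = other[, 2L],
                            extraversion = extraversion,
                            agreeableness = other[, 3L],
                            neuroticism = other[, 4L])
  structure(list(stimulus = stimulus, records = records,
                 personality = personality, true_L = true_L,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d participants on a %d-node stimulus (L ~ N(%g, %g^2))\n",
    nrow(x$records), igraph::gorder(x$stimulus),
    x$config$L_mean, x$config$L_sd))
  invisible(x)
}

#' Write a cohort to a directory of plain-text files
#'
#' Emits `stimulus.edgelist`, `stimulus.graphml`, `choices.csv`,
#' `personality.csv`, a `manifest.json` with the config, and — clearly
#' separated from the pipeline inputs — `truth.csv` with the generative
#' per-participant L.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_edgelist(cohort$stimulus, file.path(dir, "stimulus.edgelist"))
  write_graphml(cohort$stimulus, file.path(dir, "stimulus.graphml"))
  utils::write.csv(cohort$records, file.path(dir, "choices.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$personality, file.path(dir, "personality.csv"),
                   row.names = FALSE)
  if (length(cohort$true_L)) {
    utils::write.csv(
      data.frame(participant_id = cohort$records$participant_id,
                 true_L = cohort$true_L),
      file.path(dir, "truth.csv"), row.names = FALSE)
  }
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' `truth.csv` is optional: without it the cohort loads in
#' pipeline-facing mode with an empty `true_L`.
#'
#' @param dir cohort directory.
#' @return a `synthetic_cohort`.
#' @export
read_cohort <- function(dir) {
  need <- c("stimulus.edgelist", "choices.csv", "personality.csv")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) {
      stop("cohort directory is missing ", f)
    }
  }
  stimulus <- read_edgelist(file.path(dir, "stimulus.edgelist"))
  records <- utils::read.csv(file.path(dir, "choices.csv"))
  personality <- utils::read.csv(file.path(dir, "personality.csv"))
  truth_path <- file.path(dir, "truth.csv")
  true_L <- if (file.exists(truth_path)) {
    utils::read.csv(truth_path)$true_L
  } else {
    numeric(0)
  }
  manifest_path <- file.path(dir, "manifest.json")
  config <- if (file.exists(manifest_path)) {
    cfg <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    structure(cfg, class = "cohort_config")
  } else {
    NULL
  }
  structure(list(stimulus = stimulus, records = records,
                 personality = personality, true_L = true_L,
                 config = config),
            class = "synthetic_cohort")
}
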