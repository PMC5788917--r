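#' Configuration of a simulated group rating experiment
#'
#' Describes the structure of the experiment the simulator emulates:
#' several groups of raters who each rate the same within-group stimulus
#' set, balanced across the three stimulus conditions, in blocks, with the
#' displayed social information formed from peers' initial ratings under
#' one of three rules.
#'
#' @param n_groups Number of groups (default 6, as in the original study).
#' @param group_sizes Optional integer vector of length `n_groups` giving
#'   exact group sizes; when `NULL`, sizes are drawn uniformly from
#'   `group_size_range` at simulation time.
#' @param group_size_range Integer pair within `[5, 10]`; range of group
#'   sizes when `group_sizes` is `NULL`.
#' @param condition_counts Named counts of trials per condition for each
#'   participant (default 10 each of face, hand, art). Their sum is the
#'   number of trials per participant (default 30).
#' @param block_scheme `"three_blocks_of_10"`, `"six_blocks_of_5"`, or
#'   `"mixed"`; `"mixed"` assigns three blocks of 10 to two thirds of the
#'   groups (rounded up) and six blocks of 5 to the rest, mirroring the
#'   4/6 vs 2/6 split of the original design.
#' @param rule_probs Probabilities of the three peer-rating rules
#'   (`all`, `top2`, `bottom2`); must be nonnegative and sum to 1.
#' @param orientation_probs Probabilities of orientation scores 0..6 used
#'   to simulate the participant roster; the default puts mass ~6/7 on
#'   scores 0--1, matching the 42-of-49 retention of the original sample.
#' @param initial_mean,image_sd,rater_sd Law of simulated initial ratings
#'   on the logit scale: `logit(initial_u) = initial_mean + q_img + e`,
#'   with image-quality effect `q_img ~ N(0, image_sd^2)` shared by all
#'   raters of an image and rater noise `e ~ N(0, rater_sd^2)`. The image
#'   effect induces between-rater agreement, so the top2/bottom2 rules
#'   generate genuinely different social information.
#' @return An object of class `experiment_design`.
#' @seealso [simulate_experiment()], [true_parameters()]
#' @export
experiment_design <- function(n_groups = 6,
                              group_sizes = NULL,
                              group_size_range = c(5, 10),
                              condition_counts = c(face = 10, hand = 10,
                                                   art = 10),
                              block_scheme = c("mixed", "three_blocks_of_10",
                                               "six_blocks_of_5"),
                              rule_probs = c(all = 1 / 3, top2 = 1 / 3,
                                             bottom2 = 1 / 3),
                              orientation_probs = c(0.66, 0.20, 0.05, 0.03,
                                                    0.02, 0.02, 0.02),
                              initial_mean = 0,
                              image_sd = 0.7,
                              rater_sd = 1.0) {
  block_scheme <- match.arg(block_scheme)
  stopifnot(n_groups >= 1)
  if (!is.null(group_sizes)) {
    stopifnot(length(group_sizes) == n_groups, all(group_sizes >= 2))
  } else {
    stopifnot(length(group_size_range) == 2,
              group_size_range[1] >= 5, group_size_range[2] <= 10,
              group_size_range[1] <= group_size_range[2])
  }
  if (is.null(names(condition_counts)) ||
      !setequal(names(condition_counts), CONDITIONS)) {
    stop("condition_counts must be named with: ",
         paste(CONDITIONS, collapse = ", "), call. = FALSE)
  }
  condition_counts <- condition_counts[CONDITIONS]
  if (is.null(names(rule_probs)) || !setequal(names(rule_probs), SOCIAL_RULES)) {
    stop("rule_probs must be named with: ",
         paste(SOCIAL_RULES, collapse = ", "), call. = FALSE)
  }
  rule_probs <- rule_probs[SOCIAL_RULES]
  if (any(rule_probs < 0) || abs(sum(rule_probs) - 1) > 1e-12) {
    stop("rule_probs must be nonnegative and sum to 1", call. = FALSE)
  }
  if (length(orientation_probs) != 7 || any(orientation_probs < 0)) {
    stop("orientation_probs must be 7 nonnegative probabilities",
         call. = FALSE)
  }
  trials_pp <- sum(condition_counts)
  structure(list(n_groups = n_groups, group_sizes = group_sizes,
                 group_size_range = group_size_range,
                 condition_counts = condition_counts,
                 trials_per_participant = trials_pp,
                 block_scheme = block_scheme, rule_probs = rule_probs,
                 orientation_probs = orientation_probs / sum(orientation_probs),
                 initial_mean = initial_mean, image_sd = image_sd,
                 rater_sd = rater_sd),
            class = "experiment_design")
}

#' Generative parameters for the simulated experiment
#'
#' The simulator draws each participant's social-influence value as
#' `s = beta[condition] + u_p` with `u_p ~ N(0, sigma_u^2)`, and final
#' ratings from `Beta(mu * phi, (1 - mu) * phi)` where `mu` interpolates
#' between the initial and social rating on the logit scale (see
#' [predicted_mean()]).
#'
#' @param beta Named vector of condition-level social influence values.
#'   The default `(0.13, 0.13, 0.14)` is the operating point reported for
#'   the face/hand/art conditions in the study this package models.
#' @param sigma_u Standard deviation of the participant random effect
#'   (default `sqrt(0.06)`, i.e. the reported random-effect variance).
#' @param phi Beta-likelihood precision (> 0). Not a reported quantity;
#'   the default 30 gives mid-scale rating noise of about 4--5 slider
#'   points, consistent with the strong in-sample fit the study reports.
#' @return An object of class `true_parameters`.
#' @export
true_parameters <- function(beta = c(face = 0.13, hand = 0.13, art = 0.14),
                            sigma_u = sqrt(0.06),
                            phi = 30) {
  if (is.null(names(beta)) || !setequal(names(beta), CONDITIONS)) {
    stop("beta must be named with: ", paste(CONDITIONS, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(sigma_u >= 0, phi > 0)
  structure(list(beta = beta[CONDITIONS], sigma_u = sigma_u, phi = phi),
            class = "true_parameters")
}

#' Social information displayed to a rater
#'
#' Computes the peer rating shown to a participant from the initial
#' ratings of the other group members: the mean of all of them
#' (`"all"`), of the two highest (`"top2"`), or of the two lowest
#' (`"bottom2"`).
#'
#' @param peer_ratings Numeric vector of at least two peers' raw ratings.
#' @param rule One of `"all"`, `"top2"`, `"bottom2"`.
#' @return The displayed rating (a single number on the raw scale).
#' @examples
#' social_information(c(10, 20, 30, 40), "top2")
#' @export
social_information <- function(peer_ratings, rule) {
  rule <- match.arg(rule, SOCIAL_RULES)
  if (length(peer_ratings) < 2) {
    stop("social information needs at least 2 peer ratings", call. = FALSE)
  }
  switch(rule,
         all = mean(peer_ratings),
         top2 = mean(sort(peer_ratings, decreasing = TRUE)[1:2]),
         bottom2 = mean(sort(peer_ratings)[1:2]))
}

block_lengths <- function(scheme, trials_pp) {
  if (scheme == "three_blocks_of_10") rep(10L, trials_pp / 10)
  else rep(5L, trials_pp / 5)
}

#' Simulate a full group rating experiment
#'
#' Generates a [social_dataset()] from the generative model with known
#' parameters: group rosters, per-group stimulus sets balanced across
#' conditions, initial ratings with a shared image-quality component,
#' social information computed from peers' initial ratings under a rule
#' drawn i.i.d. per trial, and final ratings drawn from the beta
#' observation law with `s = beta[condition] + u_p`. The same seed always
#' reproduces the identical dataset.
#'
#' @param design An [experiment_design()].
#' @param truth A [true_parameters()].
#' @param seed Integer seed controlling every random draw.
#' @return A `social_dataset` whose trial order is participant-major
#'   within group.
#' @examples
#' d <- simulate_experiment(experiment_design(n_groups = 1,
#'                                            group_sizes = 6),
#'                          true_parameters(), seed = 7)
#' table(d$trials$condition)
#' @export
simulate_experiment <- function(design, truth, seed = 1) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(truth, "true_parameters"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  sizes <- design$group_sizes
  if (is.null(sizes)) {
    sizes <- sample(seq(design$group_size_range[1],
                        design$group_size_range[2]),
                    design$n_groups, replace = TRUE)
  }
  schemes <- switch(design$block_scheme,
    mixed = {
      n10 <- ceiling(2 * design$n_groups / 3)
      c(rep("three_blocks_of_10", n10),
        rep("six_blocks_of_5", design$n_groups - n10))
    },
    rep(design$block_scheme, design$n_groups))

  trials_pp <- design$trials_per_participant
  all_trials <- vector("list", design$n_groups)
  parts <- vector("list", design$n_groups)

  for (g in seq_len(design$n_groups)) {
    P <- sizes[g]
    gid <- sprintf("G%02d", g)
    pids <- sprintf("%s_P%02d", gid, seq_len(P))
    scores <- sample(0:6, P, replace = TRUE, prob = design$orientation_probs)
    parts[[g]] <- data.frame(participant_id = pids, group_id = gid,
                             orientation_score = scores,
                             stringsAsFactors = FALSE)

    # One stimulus set per group, balanced across conditions; every member
    # rates every image (synchronous blocks).
    img_cond <- rep(CONDITIONS, times = design$condition_counts)
    image_id <- sprintf("%s_%s%02d", gid, img_cond,
                        unlist(lapply(design$condition_counts, seq_len)))
    ord <- sample.int(trials_pp)         # random allocation into blocks
    img_cond <- img_cond[ord]; image_id <- image_id[ord]
    lens <- block_lengths(schemes[g], trials_pp)
    block <- rep(seq_along(lens), times = lens)

    # Initial ratings: logit-scale image effect + rater noise.
    q_img <- stats::rnorm(trials_pp, 0, design$image_sd)
    eta <- design$initial_mean +
      matrix(q_img, nrow = P, ncol = trials_pp, byrow = TRUE) +
      matrix(stats::rnorm(P * trials_pp, 0, design$rater_sd), nrow = P)
    init_u <- stats::plogis(eta)                       # P x trials
    init_raw <- pmin(pmax(unit_to_rating(pmin(pmax(init_u, UNIT_OFFSET),
                                              1 - UNIT_OFFSET)), 0), 100)
    init_u <- rating_to_unit(init_raw)                 # stored scale

    u_p <- stats::rnorm(P, 0, truth$sigma_u)

    rows <- vector("list", P)
    for (p in seq_len(P)) {
      rule <- sample(SOCIAL_RULES, trials_pp, replace = TRUE,
                     prob = design$rule_probs)
      soc_raw <- numeric(trials_pp)
      for (j in seq_len(trials_pp)) {
        soc_raw[j] <- social_information(init_raw[-p, j], rule[j])
      }
      soc_u <- rating_to_unit(soc_raw)
      s <- truth$beta[img_cond] + u_p[p]
      mu <- stats::plogis(stats::qlogis(init_u[p, ]) +
                            s * (stats::qlogis(soc_u) -
                                   stats::qlogis(init_u[p, ])))
      fin_u <- stats::rbeta(trials_pp, mu * truth$phi, (1 - mu) * truth$phi)
      fin_u <- pmin(pmax(fin_u, UNIT_OFFSET), 1 - UNIT_OFFSET)
      fin_raw <- pmin(pmax(unit_to_rating(fin_u), 0), 100)
      rows[[p]] <- data.frame(
        participant_id = pids[p], group_id = gid, block_index = block,
        condition = img_cond, image_id = image_id, social_rule = rule,
        initial_raw = init_raw[p, ], social_raw = soc_raw,
        final_raw = fin_raw, stringsAsFactors = FALSE)
    }
    all_trials[[g]] <- do.call(rbind, rows)
  }

  social_dataset(do.call(rbind, all_trials), do.call(rbind, parts))
}

#' Tabulate every image's initial ratings by participant
#'
#' Builds, per image, the named vector of initial ratings given by each
#' member of the image's group. Used to audit that recorded social
#' information is reproducible from peers' initial ratings.
#'
#' @param dataset A [social_dataset()] (or trial data frame) in which
#'   every image was rated by every member of its group.
#' @return A named list: one numeric vector (participant -> initial
#'   rating) per image id.
#' @export
peer_rating_table <- function(dataset) {
  trials <- if (inherits(dataset, "social_dataset")) dataset$trials else dataset
  if (nrow(trials) == 0) return(structure(list(), names = character(0)))
  group_of <- tapply(trials$group_id, trials$image_id, function(x) x[1])
  members <- split(unique(trials[, c("participant_id", "group_id")])$participant_id,
                   unique(trials[, c("participant_id", "group_id")])$group_id)
  out <- lapply(split(trials, trials$image_id), function(tt) {
    stats::setNames(tt$initial_raw, tt$participant_id)
  })
  for (img in names(out)) {
    missing <- setdiff(members[[group_of[[img]]]], names(out[[img]]))
    if (length(missing)) {
      stop(sprintf("image %s lacks initial ratings from: %s", img,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  out
}

#' Audit recorded social information against peers' initial ratings
#'
#' Recomputes, for every trial, the social information implied by the
#' recorded rule and the peers' initial ratings, and compares it with the
#' stored `social_raw`.
#'
#' @param dataset A [social_dataset()].
#' @param tol Numeric tolerance for the comparison.
#' @return A data frame of flagged trials (zero rows when the audit
#'   passes) with columns `participant_id`, `image_id`, `social_rule`,
#'   `social_raw`, `expected`.
#' @export
audit_social_information <- function(dataset, tol = 1e-9) {
  trials <- if (inherits(dataset, "social_dataset")) dataset$trials else dataset
  if (nrow(trials) == 0) {
    return(data.frame(participant_id = character(0), image_id = character(0),
                      social_rule = character(0), social_raw = numeric(0),
                      expected = numeric(0)))
  }
  ratings <- peer_rating_table(dataset)
  expected <- vapply(seq_len(nrow(trials)), function(i) {
    r <- ratings[[trials$image_id[i]]]
    social_information(r[names(r) != trials$participant_id[i]],
                       trials$social_rule[i])
  }, numeric(1))
  bad <- which(abs(expected - trials$social_raw) > tol)
  data.frame(participant_id = trials$participant_id[bad],
             image_id = trials$image_id[bad],
             social_rule = trials$social_rule[bad],
             social_raw = trials$social_raw[bad],
             expected = expected[bad],
             stringsAsFactors = FALSE)
}
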