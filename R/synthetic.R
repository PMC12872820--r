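# Seeded generator of multistable dwell-escape dynamics with ground-truth
# labels. The hidden state follows a Markov chain over m attractors; dwell
# durations are geometric (memoryless) with mean tau steps; escapes traverse
# linearly between consecutive attractor centers over e steps. Enforced
# separation of time scales (tau >= 5 e) and attractor separability
# (Delta >= 6 sigma) make the generated series satisfy the modeling premise
# that transitions are sudden relative to within-state drift.

#' Configuration for the multistable dwell-escape generator
#'
#' @param m number of attractor states.
#' @param D state-space dimensionality (default 4, mirroring dyadic
#'   warmth/dominance coding for patient and therapist).
#' @param T_points series length (number of samples).
#' @param dt sampling interval in seconds (default 0.5).
#' @param centers optional m x D matrix of attractor centers; auto-placed
#'   uniformly in \[-800, 800\]^D with minimum pairwise separation
#'   `min_separation` when omitted (range chosen inside the \[-1000, 1000\]
#'   coding scale so noise rarely clips).
#' @param transition_matrix m x m row-stochastic matrix with zero diagonal;
#'   default is uniform over the other states.
#' @param mean_dwell_steps mean dwell duration tau in steps; scalar or
#'   length-m vector (per-state). Must satisfy `tau >= 5 * escape_steps`.
#' @param escape_steps number of interpolation steps e of an escape.
#' @param noise_sd isotropic Gaussian observation noise sigma; defaults to
#'   `Delta / 10` where Delta is the minimum pairwise center distance. Must
#'   satisfy `Delta >= 6 * sigma`.
#' @param seed integer RNG seed; the whole simulation is reproducible from it.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(m, D = 4, T_points = 3000, dt = 0.5,
                             centers = NULL, transition_matrix = NULL,
                             mean_dwell_steps = 150, escape_steps = 2,
                             noise_sd = NULL, min_separation = 600, seed = 1) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop_config("'m' must be a positive integer")
  if (T_points < 2L) stop_config("'T_points' must be >= 2")
  if (is.null(centers)) {
    centers <- place_centers(m, D, min_separation, seed)
  } else {
    centers <- as.matrix(centers)
    if (nrow(centers) != m || ncol(centers) != D) {
      stop_config("'centers' must be an m x D matrix")
    }
  }
  delta <- if (m > 1L) min(stats::dist(centers)) else Inf
  if (is.null(noise_sd)) noise_sd <- if (is.finite(delta)) delta / 10 else 1
  if (is.finite(delta) && delta < 6 * noise_sd) {
    stop_config("attractor separation (", round(delta, 2),
                ") must be >= 6 * noise_sd (", 6 * noise_sd, ")")
  }
  tau <- rep_len(as.double(mean_dwell_steps), m)
  if (any(tau < 5 * escape_steps)) {
    stop_config("mean_dwell_steps must be >= 5 * escape_steps ",
                "(separation of time scales)")
  }
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(if (m > 1L) 1 / (m - 1) else 0, m, m)
    diag(transition_matrix) <- 0
  } else {
    transition_matrix <- as.matrix(transition_matrix)
    if (nrow(transition_matrix) != m || ncol(transition_matrix) != m) {
      stop_config("'transition_matrix' must be m x m")
    }
    if (any(diag(transition_matrix) != 0)) {
      stop_config("'transition_matrix' must have a zero diagonal")
    }
    if (m > 1L && any(abs(rowSums(transition_matrix) - 1) > 1e-9)) {
      stop_config("'transition_matrix' rows must sum to 1")
    }
  }
  structure(
    list(m = m, D = as.integer(D), T_points = as.integer(T_points),
         dt = as.double(dt), centers = centers,
         transition_matrix = transition_matrix, mean_dwell_steps = tau,
         escape_steps = as.integer(escape_steps),
         noise_sd = as.double(noise_sd), min_separation = delta,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Seeded rejection placement of m centers with minimum pairwise separation.
place_centers <- function(m, D, min_separation, seed) {
  with_seed(seed + 104729L, {
    centers <- matrix(stats::runif(D, -800, 800), nrow = 1L)
    tries <- 0L
    while (nrow(centers) < m) {
      cand <- stats::runif(D, -800, 800)
      dd <- sqrt(colSums((t(centers) - cand)^2))
      if (all(dd >= min_separation)) centers <- rbind(centers, cand)
      tries <- tries + 1L
      if (tries > 10000L) {
        stop_config("could not place ", m, " centers at separation ",
                    min_separation, " in D = ", D)
      }
    }
    dimnames(centers) <- NULL
    centers
  })
}

#' Named generator scenarios
#'
#' * `easy-3-state`: three well-separated attractors on a deterministic
#'   cycle (tau = 150 steps, e = 2, sigma = Delta/10, T = 3000), the
#'   calibration scenario for parameter recovery.
#' * `hard-5-state`: five auto-placed attractors, uniform random switching,
#'   shorter dwells and stronger noise (tau = 60, e = 3, sigma = Delta/7).
#' * `null-no-coupling`: easy-3-state dynamics with an annotation level that
#'   is pure noise around the scale midpoint, independent of the hidden
#'   state (for type-I calibration).
#' * `planted-effect`: three attractors with per-state mean dwells
#'   (60, 150, 375 steps) and annotation levels (1, 3, 5) increasing with
#'   dwell, so longer-dwelling states carry higher ratings (for power and
#'   sign-recovery checks).
#'
#' @param name one of the scenario names above.
#' @param seed RNG seed forwarded to the config.
#' @param T_points optional series-length override.
#' @return list with `$config` (a [generator_config()]) and `$annotation`
#'   (list with `levels` per state or `NULL` for state-independent noise,
#'   `noise_sd`, `interval_length`).
#' @export
preset_config <- function(name = c("easy-3-state", "hard-5-state",
                                   "null-no-coupling", "planted-effect"),
                          seed = 1, T_points = NULL) {
  name <- match.arg(name)
  cycle3 <- matrix(c(0, 1, 0,
                     0, 0, 1,
                     1, 0, 0), nrow = 3, byrow = TRUE)
  centers3 <- matrix(c( 600,  600, 0, 0,
                       -600,  600, 0, 0,
                          0, -600, 0, 0), nrow = 3, byrow = TRUE)
  if (name == "easy-3-state") {
    cfg <- generator_config(3, D = 4, T_points = T_points %||% 3000,
                            centers = centers3, transition_matrix = cycle3,
                            mean_dwell_steps = 150, escape_steps = 2,
                            noise_sd = 120, seed = seed)
    ann <- list(levels = c(1, 3, 5), noise_sd = 0.3, interval_length = 30)
  } else if (name == "hard-5-state") {
    cfg <- generator_config(5, D = 4, T_points = T_points %||% 4000,
                            mean_dwell_steps = 60, escape_steps = 3,
                            noise_sd = NULL, min_separation = 700, seed = seed)
    cfg$noise_sd <- cfg$min_separation / 7
    if (cfg$min_separation < 6 * cfg$noise_sd) {
      stop_config("preset separation check failed")   # cannot happen: 7 > 6
    }
    ann <- list(levels = seq(1, 5, length.out = 5), noise_sd = 0.5,
                interval_length = 30)
  } else if (name == "null-no-coupling") {
    cfg <- generator_config(3, D = 4, T_points = T_points %||% 3000,
                            centers = centers3, transition_matrix = cycle3,
                            mean_dwell_steps = 150, escape_steps = 2,
                            noise_sd = 120, seed = seed)
    ann <- list(levels = NULL, noise_sd = 0.8, interval_length = 30)
  } else {   # planted-effect
    cfg <- generator_config(3, D = 4, T_points = T_points %||% 3000,
                            centers = centers3, transition_matrix = cycle3,
                            mean_dwell_steps = c(60, 150, 375),
                            escape_steps = 2, noise_sd = 120, seed = seed)
    ann <- list(levels = c(1, 3, 5), noise_sd = 0.5, interval_length = 30)
  }
  list(config = cfg, annotation = ann)
}

#' Simulate a dwell-escape session with ground truth
#'
#' Realizes the hidden Markov chain of `cfg`: geometric dwells (mean tau,
#' minimum 1 step) at each attractor center plus iid Gaussian noise, and
#' sudden escapes interpolating linearly between consecutive centers over
#' `escape_steps` samples (plus the same noise). Fully reproducible from
#' `cfg$seed`.
#'
#' @param cfg a [generator_config()].
#' @param session_id identifier for the emitted session.
#' @return list with `session` (a `ts_session`; channels named
#'   patient/therapist warmth/dominance when D = 4) and `ground_truth`
#'   (class `synthetic_ground_truth`: `state_labels` of length T with `NA`
#'   during escapes, `visit_sequence`, and the m x m matrix
#'   `transition_counts` of realized attractor-to-attractor transitions).
#' @export
simulate_session <- function(cfg, session_id = "synthetic") {
  stopifnot(inherits(cfg, "generator_config"))
  m <- cfg$m; Tn <- cfg$T_points; e <- cfg$escape_steps
  with_seed(cfg$seed, {
    vals <- matrix(NA_real_, nrow = Tn, ncol = cfg$D)
    labels <- rep(NA_integer_, Tn)
    pos <- 0L
    state <- if (m > 1L) sample.int(m, 1L) else 1L
    while (pos < Tn) {
      dwell_len <- stats::rgeom(1L, 1 / cfg$mean_dwell_steps[state]) + 1L
      take <- min(dwell_len, Tn - pos)
      if (take > 0L) {
        rows <- pos + seq_len(take)
        vals[rows, ] <- rep(cfg$centers[state, ], each = take) +
          stats::rnorm(take * cfg$D, 0, cfg$noise_sd)
        labels[rows] <- state
        pos <- pos + take
      }
      if (pos >= Tn || m == 1L) break
      nxt <- sample.int(m, 1L, prob = cfg$transition_matrix[state, ])
      take <- min(e, Tn - pos)
      if (take > 0L) {
        frac <- seq_len(take) / (e + 1)
        interp <- (1 - frac) %o% cfg$centers[state, ] +
          frac %o% cfg$centers[nxt, ]
        rows <- pos + seq_len(take)
        vals[rows, ] <- interp + stats::rnorm(take * cfg$D, 0, cfg$noise_sd)
        pos <- pos + take
      }
      state <- nxt
    }
    ch <- if (cfg$D == 4L) {
      c("patient_warmth", "therapist_warmth",
        "patient_dominance", "therapist_dominance")
    } else paste0("ch", seq_len(cfg$D))
    session <- time_series_session(vals, dt = cfg$dt, channel_names = ch,
                                   session_id = session_id)
    dwell_runs <- rle(ifelse(is.na(labels), -1L, labels))
    visits <- dwell_runs$values[dwell_runs$values > 0L]
    counts <- matrix(0L, m, m)
    if (length(visits) > 1L) {
      for (i in seq_len(length(visits) - 1L)) {
        counts[visits[i], visits[i + 1L]] <- counts[visits[i], visits[i + 1L]] + 1L
      }
    }
    gt <- structure(
      list(state_labels = labels, visit_sequence = as.integer(visits),
           transition_counts = counts, m = m),
      class = "synthetic_ground_truth"
    )
    list(session = session, ground_truth = gt)
  })
}

#' Interval-coded annotation coupled to the hidden state
#'
#' Emulates observer-coded ratings at fixed intervals (30 s in typical
#' rupture coding): each interval's rating is the mean of `per_state_level`
#' over the states occupying its time points (escape points carry the
#' preceding dwell state's level), plus Gaussian noise clipped to the scale.
#' With `per_state_level = NULL` the rating is state-independent noise
#' around the scale midpoint (the null scenario).
#'
#' @param gt a `synthetic_ground_truth`.
#' @param session the matching `ts_session`.
#' @param per_state_level numeric vector of length m mapping each state to a
#'   rating level, or `NULL` for no coupling.
#' @param interval_length interval duration in seconds (default 30).
#' @param noise_sd rating noise standard deviation.
#' @param seed RNG seed for the noise (`NULL` uses the current RNG stream).
#' @param track_name,scale_min,scale_max passed to [annotation_track()].
#' @return an `annotation_track`.
#' @export
coupled_annotation <- function(gt, session, per_state_level,
                               interval_length = 30, noise_sd = 0,
                               seed = NULL, track_name = "rating",
                               scale_min = 1, scale_max = 5) {
  Tn <- n_points(session)
  if (length(gt$state_labels) != Tn) stop_data("ground truth length != T")
  eff <- fill_forward(gt$state_labels)
  starts <- seq(session$times[1L], session$times[Tn], by = interval_length)
  idx <- pmin(floor((session$times - starts[1L] + 1e-9) / interval_length) + 1L,
              length(starts))
  base <- if (is.null(per_state_level)) {
    rep((scale_min + scale_max) / 2, length(starts))
  } else {
    if (length(per_state_level) != gt$m) {
      stop_config("'per_state_level' must have one level per state")
    }
    if (any(per_state_level < scale_min) || any(per_state_level > scale_max)) {
      stop_config("state levels must lie within the rating scale")
    }
    as.vector(tapply(per_state_level[eff], idx, mean))
  }
  with_seed(seed, {
    ratings <- base + if (noise_sd > 0) {
      stats::rnorm(length(base), 0, noise_sd)
    } else 0
    ratings <- pmin(pmax(ratings, scale_min), scale_max)
    annotation_track(ratings, interval_starts = starts,
                     interval_length = interval_length,
                     track_name = track_name,
                     scale_min = scale_min, scale_max = scale_max)
  })
}

# Carry the last non-NA value forward (simulations always start in a dwell).
fill_forward <- function(x) {
  ok <- !is.na(x)
  if (!ok[1L]) stop_data("sequence starts with an undefined state")
  x[cummax(seq_along(x) * ok)]
}

#' Score recovery of the planted attractor structure
#'
#' Compares a transition network built from a simulated session against the
#' generator's ground truth. `ari` is the adjusted Rand index between node
#' membership and the hidden dwell-state labels, restricted to dwell time
#' points (escape points are genuinely ambiguous and excluded).
#' `edge_recall` is the fraction of realized attractor-to-attractor
#' transitions (ordered state pairs with at least one realized transition)
#' that appear as a network edge between nodes whose majority label matches
#' the pair. For majority labeling, escape points carry the label of the
#' dwell state they leave, so a node made of transition-path points counts
#' toward its source state and the edge it sends into the destination
#' attractor realizes the pair.
#'
#' @param net a `transition_network` built from the simulated session.
#' @param gt the matching `synthetic_ground_truth`.
#' @return list with `ari` and `edge_recall` (`NA` when no transition was
#'   realized).
#' @export
recovery_score <- function(net, gt) {
  Tn <- net$provenance$T
  if (length(gt$state_labels) != Tn) stop_data("ground truth length != T")
  memb <- node_membership(net)
  dwell <- !is.na(gt$state_labels)
  ari <- mclust::adjustedRandIndex(memb[dwell], gt$state_labels[dwell])

  eff <- fill_forward(gt$state_labels)   # escapes belong to the state they leave
  maj <- vapply(net$nodes, function(members) {
    tab <- table(eff[members])
    as.integer(names(tab)[which.max(tab)])   # ties: smaller state id
  }, integer(1))

  realized <- which(gt$transition_counts > 0, arr.ind = TRUE)
  if (!nrow(realized)) {
    return(list(ari = ari, edge_recall = NA_real_))
  }
  ef <- maj[net$edges$from]
  et <- maj[net$edges$to]
  hit <- vapply(seq_len(nrow(realized)), function(r) {
    any(!is.na(ef) & !is.na(et) &
          ef == realized[r, 1L] & et == realized[r, 2L])
  }, logical(1))
  list(ari = ari, edge_recall = mean(hit))
}
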