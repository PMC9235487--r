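# Anchor rules ---------------------------------------------------------------
#
# An anchor is a conjunction of (position, symbol) predicates over the fixed
# frame, plus a predicted class.  Its precision is the probability that a
# perturbation of the explained instance satisfying the rule receives the
# same model prediction; anchors are grown bottom-up by best-arm
# identification (KL-LUCB) until the precision lower bound clears the
# threshold.

#' Build a predicate set
#'
#' @param position Integer vector of 0-based frame positions.
#' @param symbol Character vector of frame symbols (reserved tokens allowed).
#' @return Data frame with columns `position`, `symbol`, ordered by position.
#' @export
predicates <- function(position = integer(0), symbol = character(0)) {
  stopifnot(length(position) == length(symbol))
  p <- data.frame(position = as.integer(position),
                  symbol = as.character(symbol), stringsAsFactors = FALSE)
  if (anyDuplicated(p$position)) stop("at most one predicate per position")
  p[order(p$position), , drop = FALSE]
}

#' Anchor search parameters
#'
#' Defaults follow the published regime: precision threshold 0.9,
#' delta = 0.3, tau = 0.3.
#'
#' @param precision_threshold Required precision lower bound, in (0, 1].
#' @param delta Bandit failure probability, in (0, 1).
#' @param tau Best-arm tolerance, in (0, 1).
#' @param beam_width Number of rules kept per round (1 = greedy).
#' @param batch_size Perturbations per bandit pull.
#' @param max_predicates Cap on rule length (default: frame length at run
#'   time).
#' @param max_pulls Total bandit-pull budget per anchor; on exhaustion the
#'   best rule so far is returned flagged below threshold.
#' @param bound `"kl"` (Kullback-Leibler/Chernoff, default) or `"hoeffding"`
#'   confidence bounds.
#' @param seed Random seed.
#' @return An object of class `anchor_params`.
#' @export
anchor_params <- function(precision_threshold = 0.9, delta = 0.3, tau = 0.3,
                          beam_width = 1L, batch_size = 100L,
                          max_predicates = NULL, max_pulls = 20000L,
                          bound = c("kl", "hoeffding"), seed = 0L) {
  stopifnot(precision_threshold > 0, precision_threshold <= 1,
            delta > 0, delta < 1, tau > 0, tau < 1,
            beam_width >= 1L, batch_size >= 1L)
  structure(list(precision_threshold = precision_threshold, delta = delta,
                 tau = tau, beam_width = as.integer(beam_width),
                 batch_size = as.integer(batch_size),
                 max_predicates = max_predicates,
                 max_pulls = as.integer(max_pulls),
                 bound = match.arg(bound), seed = as.integer(seed)),
            class = "anchor_params")
}

#' Does a rule apply to samples?
#'
#' True iff, for every predicate, the frame symbol at that position equals
#' the predicate symbol.  The empty rule applies to everything.
#'
#' @param rule An `anchor_rule` or a predicate data frame.
#' @param samples A `seq_set`.
#' @return Logical vector, one entry per sample.
#' @export
rule_applies <- function(rule, samples) {
  p <- if (inherits(rule, "anchor_rule")) rule$predicates else rule
  stopifnot(inherits(samples, "seq_set"))
  frame <- frame_matrix(samples)
  out <- rep(TRUE, nrow(frame))
  for (i in seq_len(nrow(p))) {
    out <- out & frame[, p$position[i] + 1L] == p$symbol[i]
  }
  unname(out)
}

#' Coverage of a rule over a sample set
#'
#' @param rule An `anchor_rule` or predicate data frame.
#' @param samples A non-empty `seq_set`.
#' @return Fraction of samples satisfying the rule, in \[0, 1\].
#' @export
rule_coverage <- function(rule, samples) {
  if (n_samples(samples) == 0L) stop("empty sample list")
  mean(rule_applies(rule, samples))
}

#' Sample perturbations of an instance
#'
#' Every fixed position keeps the instance's symbol; every other position is,
#' independently with probability 0.5, replaced by a draw from the pool's
#' empirical per-position symbol distribution (otherwise kept).  This
#' preserves the positional composition of the repertoire while exploring
#' the model's behaviour around the instance.
#'
#' @param instance A single-sample `seq_set` (or the first sample is used).
#' @param fixed Integer vector of 0-based positions to hold fixed.
#' @param pool Non-empty `seq_set` supplying the empirical distribution.
#' @param n Number of perturbations (> 0).
#' @param seed Random seed.
#' @return A `seq_set` of `n` perturbed frames (ids `p1`, ..., `pn`).
#' @export
sample_perturbations <- function(instance, fixed, pool, n, seed = 0L) {
  if (n <= 0L) stop("n must be positive")
  if (n_samples(pool) == 0L) stop("perturbation pool is empty")
  inst <- frame_matrix(instance)[1L, ]
  L <- length(inst)
  if (pool$frame_length != L) stop("pool frame length mismatch")
  fixed <- as.integer(fixed)
  if (length(fixed) && (min(fixed) < 0L || max(fixed) >= L)) {
    stop("fixed positions outside the frame")
  }
  pf <- frame_matrix(pool)
  out <- matrix(rep(inst, each = n), nrow = n)
  with_seed(seed, {
    free <- setdiff(seq_len(L) - 1L, fixed)
    for (pos in free) {
      col <- pf[, pos + 1L]
      resample <- stats::runif(n) < 0.5
      k <- sum(resample)
      if (k) out[resample, pos + 1L] <- col[sample.int(length(col), k,
                                                       replace = TRUE)]
    }
  })
  perturbation_set(out, instance)
}

# wrap a frame matrix as a seq_set without re-deriving raw strings from
# residues (perturbed frames may hold reserved tokens anywhere)
perturbation_set <- function(frame, template) {
  ids <- paste0("p", seq_len(nrow(frame)))
  rownames(frame) <- ids
  raw <- apply(frame, 1L, function(r)
    paste(r[!r %in% reserved_tokens()], collapse = ""))
  structure(list(ids = ids, frame = frame, raw = stats::setNames(raw, ids),
                 alphabet = template$alphabet,
                 frame_length = template$frame_length,
                 start_stop = template$start_stop, regions = NULL),
            class = "seq_set")
}

# two-sided Bernoulli confidence bounds -------------------------------------

kl_bern <- function(p, q) {
  p <- min(max(p, 1e-12), 1 - 1e-12)
  q <- min(max(q, 1e-12), 1 - 1e-12)
  p * log(p / q) + (1 - p) * log((1 - p) / (1 - q))
}

# largest q <= phat with n * KL(phat, q) <= level (lower bound); smallest
# q >= phat for the upper bound.  Bisection; exact enough at 1e-8.
kl_lower <- function(phat, n, level) {
  if (n == 0L) return(0)
  lo <- 0; hi <- phat
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (n * kl_bern(phat, mid) > level) lo <- mid else hi <- mid
  }
  hi
}

kl_upper <- function(phat, n, level) {
  if (n == 0L) return(1)
  lo <- phat; hi <- 1
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (n * kl_bern(phat, mid) > level) hi <- mid else lo <- mid
  }
  lo
}

bern_bounds <- function(phat, n, level, bound = "kl") {
  if (bound == "hoeffding") {
    r <- sqrt(level / (2 * n))
    return(c(lower = max(0, phat - r), upper = min(1, phat + r)))
  }
  c(lower = kl_lower(phat, n, level), upper = kl_upper(phat, n, level))
}

#' Estimate anchor precision with confidence bounds
#'
#' Draws `n` perturbations of `instance` with the predicate positions held
#' fixed (and forced to the predicate symbols), queries the model, and
#' returns the fraction predicted as `target` together with two-sided
#' (1 - delta) Kullback-Leibler (Chernoff) confidence bounds on the
#' Bernoulli mean.
#'
#' @param preds Predicate data frame (see [predicates()]).
#' @param target Target class label.
#' @param model A `bbox_model`.
#' @param instance Single-sample `seq_set` being explained.
#' @param pool `seq_set` supplying the perturbation distribution.
#' @param n Number of perturbations (>= 1).
#' @param delta Two-sided failure probability.
#' @param seed Random seed.
#' @param bound `"kl"` or `"hoeffding"`.
#' @return List with `estimate`, `lower_bound`, `upper_bound`, `n`.
#' @export
estimate_precision <- function(preds, target, model, instance, pool, n,
                               delta = 0.3, seed = 0L, bound = "kl") {
  stopifnot(n >= 1L)
  inst <- instance
  if (nrow(preds)) {
    # force predicate symbols onto the instance so fixing positions pins them
    inst$frame[1L, preds$position + 1L] <- preds$symbol
  }
  pert <- sample_perturbations(inst, fixed = preds$position, pool = pool,
                               n = n, seed = seed)
  phat <- mean(predict_labels(model, pert) == target)
  b <- bern_bounds(phat, n, log(2 / delta), bound)
  list(estimate = phat, lower_bound = unname(b["lower"]),
       upper_bound = unname(b["upper"]), n = as.integer(n))
}

# KL-LUCB beta schedule (Kaufmann & Kalyanakrishnan as used by the original
# anchors implementation): alpha = 1.1, k = 405.5
lucb_beta <- function(t, n_arms, delta) {
  log(405.5 * n_arms * t^1.1 / delta)
}

# arm bookkeeping: pull = one batch of perturbations through the model
make_arm_puller <- function(model, medoid, pool, batch_size, target, seed_env) {
  function(arm) {
    seed_env$counter <- seed_env$counter + 1L
    preds <- arm$preds
    pert <- sample_perturbations(
      medoid, fixed = preds$position, pool = pool, n = batch_size,
      seed = (seed_env$base + seed_env$counter) %% 2147480009)
    hits <- sum(predict_labels(model, pert) == target)
    arm$n <- arm$n + batch_size
    arm$succ <- arm$succ + hits
    arm
  }
}

arm_stats <- function(arm, beta, bound) {
  phat <- if (arm$n) arm$succ / arm$n else 0.5
  b <- bern_bounds(phat, max(arm$n, 1L), beta, bound)
  list(mean = phat, lb = unname(b["lower"]), ub = unname(b["upper"]))
}

#' Find an anchor rule for a cluster medoid
#'
#' Bottom-up beam search over candidate predicates (position, medoid symbol):
#' starting from the empty rule, each round extends every beam rule by one
#' unused position and selects the best extension(s) by KL-LUCB best-arm
#' identification on precision (tolerance `tau`, failure probability
#' `delta`), then pulls the selected rule until the precision threshold lies
#' outside its confidence interval.  The search stops when a rule's lower
#' bound clears the threshold, or when `max_predicates` / `max_pulls` is
#' reached (then the highest-lower-bound rule seen is returned, flagged
#' `below_threshold`).  Ties among equal candidates break toward higher
#' coverage, then lower position index.
#'
#' @param medoid Single-sample `seq_set` to explain (a cluster medoid).
#' @param model A `bbox_model`.
#' @param pool `seq_set` the perturbation distribution is drawn from
#'   (by default the medoid's own prediction split).
#' @param params An [anchor_params()].
#' @param source Optional list(split, cluster, medoid_id) recorded on the
#'   rule.
#' @return An object of class `anchor_rule`.
#' @export
find_anchor <- function(medoid, model, pool, params = anchor_params(),
                        source = NULL) {
  stopifnot(inherits(medoid, "seq_set"), inherits(model, "bbox_model"),
            inherits(params, "anchor_params"))
  if (medoid$frame_length != pool$frame_length) {
    stop("medoid frame length does not match the pool")
  }
  L <- medoid$frame_length
  max_preds <- if (is.null(params$max_predicates)) L
               else min(params$max_predicates, L)
  target <- predict_labels(model, medoid)[1L]
  mrow <- frame_matrix(medoid)[1L, ]
  seed_env <- new.env()
  # derived stream seeds must stay below 2^31 (R integer range)
  seed_env$base <- (as.numeric(params$seed) * 100003) %% 2147480009
  seed_env$counter <- 0L
  pull <- make_arm_puller(model, medoid, pool, params$batch_size, target,
                          seed_env)
  pulls_used <- function() seed_env$counter
  budget_left <- function() {
    pulls_used() * params$batch_size < params$max_pulls
  }

  new_arm <- function(positions) {
    list(preds = predicates(positions, mrow[positions + 1L]),
         n = 0L, succ = 0L)
  }
  coverage_of <- function(arm) mean(rule_applies(arm$preds, pool))

  # confirmatory sampling: tighten one rule until threshold is outside its CI
  confirm <- function(arm) {
    repeat {
      st <- arm_stats(arm, log(2 / params$delta), params$bound)
      if (st$lb >= params$precision_threshold ||
          st$ub < params$precision_threshold || !budget_left()) {
        return(list(arm = arm, stats = st))
      }
      arm <- pull(arm)
    }
  }

  best_seen <- NULL   # highest-lower-bound rule, for budget exhaustion
  note_best <- function(arm, st) {
    if (is.null(best_seen) || st$lb > best_seen$stats$lb) {
      best_seen <<- list(arm = arm, stats = st)
    }
  }
  finish <- function(arm, st, below) {
    p <- arm$preds
    structure(list(predicates = p, prediction = target,
                   precision_estimate = st$mean,
                   precision_lower_bound = st$lb,
                   coverage = coverage_of(arm),
                   source = source, n_samples_used = arm$n,
                   below_threshold = below),
              class = "anchor_rule")
  }

  # the empty rule first: a constant-ish model may already clear the bar
  res <- confirm(pull(new_arm(integer(0))))
  note_best(res$arm, res$stats)
  if (res$stats$lb >= params$precision_threshold) {
    return(finish(res$arm, res$stats, below = FALSE))
  }

  beam <- list(new_arm(integer(0)))
  for (round in seq_len(max_preds)) {
    # candidate extensions of every beam rule, deduplicated by position set
    cands <- list()
    for (b in beam) {
      for (pos in setdiff(seq_len(L) - 1L, b$preds$position)) {
        key <- paste(sort(c(b$preds$position, pos)), collapse = ",")
        if (is.null(cands[[key]])) {
          cands[[key]] <- new_arm(sort(c(b$preds$position, pos)))
        }
      }
    }
    cands <- unname(cands)
    if (!length(cands)) break
    top_n <- min(params$beam_width, length(cands))

    # KL-LUCB: pull until the top set is separated from the rest within tau
    cands <- lapply(cands, pull)
    repeat {
      t <- pulls_used()
      beta <- lucb_beta(max(t, 1L), length(cands), params$delta)
      st <- lapply(cands, arm_stats, beta = beta, bound = params$bound)
      means <- vapply(st, `[[`, numeric(1), "mean")
      ord <- order(-means,
                   -vapply(cands, coverage_of, numeric(1)),
                   vapply(cands, function(a) min(a$preds$position),
                          integer(1)))
      top <- ord[seq_len(top_n)]
      rest <- setdiff(ord, top)
      if (!length(rest) || !budget_left()) break
      lb_top <- vapply(st[top], `[[`, numeric(1), "lb")
      ub_rest <- vapply(st[rest], `[[`, numeric(1), "ub")
      weak <- top[which.min(lb_top)]
      chall <- rest[which.max(ub_rest)]
      if (max(ub_rest) - min(lb_top) < params$tau) break
      cands[[weak]] <- pull(cands[[weak]])
      cands[[chall]] <- pull(cands[[chall]])
    }

    beam <- cands[top]
    # check the beam's best rule against the threshold
    for (i in seq_along(beam)) {
      res <- confirm(beam[[i]])
      beam[[i]] <- res$arm
      note_best(res$arm, res$stats)
      if (res$stats$lb >= params$precision_threshold) {
        return(finish(res$arm, res$stats, below = FALSE))
      }
    }
    if (!budget_left()) break
  }
  finish(best_seen$arm, best_seen$stats, below = TRUE)
}

#' @export
print.anchor_rule <- function(x, ...) {
  cat(format_anchor(x), "\n")
  cat(sprintf("  precision %.3f (lower bound %.3f), coverage %.3f, n = %d%s\n",
              x$precision_estimate, x$precision_lower_bound, x$coverage,
              x$n_samples_used,
              if (isTRUE(x$below_threshold)) "  [below threshold]" else ""))
  invisible(x)
}

#' Render an anchor rule as IF/AND/THEN text
#'
#' @param rule An `anchor_rule`.
#' @return A single string, e.g.
#'   `"IF (amino acid C is in position 0) AND (amino acid F is in position 4)
#'    THEN the sample is binding"`.
#' @export
format_anchor <- function(rule) {
  p <- rule$predicates
  cond <- if (!nrow(p)) "(always)" else {
    paste(sprintf("(amino acid %s is in position %d)", p$symbol, p$position),
          collapse = " AND ")
  }
  paste0("IF ", cond, " THEN the sample is ", rule$prediction)
}

#' Write / read anchors as JSON lines
#'
#' One rule per line: source split/cluster/medoid, predicates as
#' `[position, symbol]` pairs, prediction, precision estimate and lower
#' bound, coverage, sample count and the below-threshold flag.
#'
#' @param rules List of `anchor_rule` objects.
#' @param path Output path.
#' @return `path` invisibly; `read_anchors_jsonl` returns the rule list.
#' @export
write_anchors_jsonl <- function(rules, path) {
  lines <- vapply(rules, function(r) {
    src <- r$source
    jsonlite::toJSON(list(
      split = if (is.null(src$split)) NA else src$split,
      cluster = if (is.null(src$cluster)) NA else src$cluster,
      medoid_id = if (is.null(src$medoid_id)) NA else src$medoid_id,
      predicates = unname(Map(function(pos, sym) list(pos, sym),
                              r$predicates$position, r$predicates$symbol)),
      prediction = r$prediction,
      precision_estimate = r$precision_estimate,
      precision_lower_bound = r$precision_lower_bound,
      coverage = r$coverage,
      n_samples_used = r$n_samples_used,
      below_threshold = isTRUE(r$below_threshold)),
      auto_unbox = TRUE, digits = NA, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_anchors_jsonl
#' @export
read_anchors_jsonl <- function(path) {
  lapply(readLines(path), function(line) {
    x <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    p <- predicates(
      vapply(x$predicates, function(q) as.integer(q[[1]]), integer(1)),
      vapply(x$predicates, function(q) as.character(q[[2]]), character(1)))
    structure(list(predicates = p, prediction = x$prediction,
                   precision_estimate = x$precision_estimate,
                   precision_lower_bound = x$precision_lower_bound,
                   coverage = x$coverage,
                   source = list(split = x$split, cluster = x$cluster,
                                 medoid_id = x$medoid_id),
                   n_samples_used = x$n_samples_used,
                   below_threshold = isTRUE(x$below_threshold)),
              class = "anchor_rule")
  })
}
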