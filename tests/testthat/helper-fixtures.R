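# Fixtures and independent oracles shared across the suite.

# Deterministic complete roster (no randomness): every field valid,
# outcome negative by default so exclusions can be staged explicitly.
make_roster <- function(n, prior = 0, missing_required = 0,
                        missing_var = "fpg") {
  stopifnot(prior + missing_required <= n)
  r <- data.frame(
    id = sprintf("R%05d", seq_len(n)),
    sex = rep(c("female", "male"), length.out = n),
    age = 30 + (seq_len(n) %% 50),
    height = 1.6, weight = 70, bmi = 70 / 1.6^2,
    waist = 90, sbp = 120, dbp = 75,
    on_htn_meds = FALSE, smoker = FALSE, corticosteroids = FALSE,
    fh_mother = FALSE, fh_father = FALSE, fh_sister = FALSE,
    fh_brother = FALSE,
    fpg = 5.0, glucose_2h = 6.0, prior_diagnosis = FALSE,
    hdl = 1.3, triglycerides = 1.4,
    stringsAsFactors = FALSE
  )
  if (prior > 0) r$prior_diagnosis[seq_len(prior)] <- TRUE
  if (missing_required > 0) {
    idx <- prior + seq_len(missing_required)
    r[[missing_var]][idx] <- NA
  }
  r
}

# Brute-force pairwise concordance: O(events x nonevents) enumeration.
auc_brute <- function(p, y) {
  pe <- p[y == 1]; pn <- p[y == 0]
  cmp <- outer(pe, pn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Exhaustive Youden maximum over a grid of all distinct values plus all
# midpoints between consecutive sorted values (rule: positive iff p >= t).
youden_brute <- function(p, y) {
  sp <- sort(unique(p))
  grid <- unique(c(sp, (sp[-1] + sp[-length(sp)]) / 2, min(sp) - 1, max(sp) + 1))
  m <- sum(y == 1); n0 <- sum(y == 0)
  js <- vapply(grid, function(t) {
    sum(p >= t & y == 1) / m + sum(p < t & y == 0) / n0 - 1
  }, numeric(1))
  max(js)
}

# Small analysis-set style prediction sets with both classes present.
random_preds <- function(n, tie_prob = 0.3) {
  repeat {
    p <- if (runif(1) < tie_prob) {
      sample(round(runif(7), 2), n, replace = TRUE)
    } else runif(n)
    y <- rbinom(n, 1, 0.3)
    if (sum(y) > 0 && sum(y) < n) return(list(p = p, y = y))
  }
}

# Miscalibrated synthetic cohort: true risk plogis(a + x), the model
# reports probabilities shifted down by `shift` on the logit scale.
miscalibrated_preds <- function(n, target_prev = 0.176, shift = 1.4929) {
  x <- rnorm(n)
  a <- uniroot(function(a) mean(plogis(a + x)) - target_prev, c(-10, 5))$root
  true_p <- plogis(a + x)
  y <- rbinom(n, 1, true_p)
  list(p = plogis(a + x - shift), y = y, true_p = true_p)
}
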