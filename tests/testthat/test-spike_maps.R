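test_that("spike detection finds injected transients at the tail rate", {
  fs <- 30000
  set.seed(21)
  dur <- 10
  x <- rnorm(dur * fs)
  # 20 biphasic 6-SD transients at known, well-separated times
  tmpl <- c(3 * sin(pi * (1:9) / 10), -6 * sin(pi * (1:21) / 22))
  t_true <- seq(0.25, dur - 0.25, length.out = 20)
  for (tt in t_true) {
    i0 <- floor(tt * fs)
    x[i0:(i0 + length(tmpl) - 1)] <- x[i0:(i0 + length(tmpl) - 1)] + tmpl
  }
  st <- detect_spikes(x, fs, k = 3.5)
  hits <- vapply(t_true, function(tt) any(abs(st$times - tt) < 1e-3),
                 logical(1))
  expect_gte(sum(hits), 19)
  # false positives consistent with the Gaussian tail rate for k ~= 3.5:
  # per-sample crossing probability 2*pnorm(-k') with k' the threshold in
  # true-noise SDs (the injected spikes inflate the estimated SD a bit)
  k_eff <- 3.5 * sd(x)
  p <- 2 * pnorm(-k_eff)
  expected_fp <- p * fs * dur
  n_fp <- length(st$times) - sum(hits)
  expect_lt(n_fp, 3 * expected_fp + 20)
  expect_gt(n_fp, expected_fp / 10)
  # subject-specific threshold factors scale the threshold linearly
  expect_equal(channel_thresholds(eng_recording(matrix(x, 1), fs,
                                                channels = data.frame(
                                                  electrode = 1L, site = 1L,
                                                  side = "L",
                                                  ground = FALSE)),
                                  k = 4),
               4 * sd(x))
  # flat signal: warning and empty train
  expect_warning(st0 <- detect_spikes(rep(0, 1000), fs), "SD")
  expect_length(st0$times, 0)
})

test_that("firing rates bin events half-open at the stated width", {
  st <- structure(list(times = seq(0.05, 0.95, by = 0.1)),
                  class = "spike_train")
  expect_equal(firing_rate(st, 0, 1, 0.1), rep(10, 10))
  expect_equal(firing_rate(structure(list(times = numeric(0)),
                                     class = "spike_train"), 0, 1, 0.1),
               rep(0, 10))
  # an event exactly on a boundary lands in the right-hand bin
  expect_equal(firing_rate(c(0.2), 0, 0.4, 0.1), c(0, 0, 10, 0))
  # spike-count conservation for arbitrary trains
  set.seed(2)
  times <- sort(runif(200, 0, 3))
  r <- firing_rate(times, 0.5, 2.5, 0.1)
  expect_equal(sum(r) * 0.1, sum(times >= 0.5 & times < 2.5))
})

test_that("modulation z-score follows its defining arithmetic", {
  expect_equal(modulation_zscore(c(10, 10), c(10, 12, 8)), 0)
  expect_equal(modulation_zscore(rep(15, 5), c(5, 10, 15)), 1)
  expect_false(modulation_zscore(c(10, 10), c(10, 12, 8)) > 0.5)
  expect_true(modulation_zscore(rep(15, 5), c(5, 10, 15)) > 0.5)
  expect_warning(z <- modulation_zscore(c(5, 5), c(1, 1)), "undefined")
  expect_equal(z, Inf)
  expect_warning(z0 <- modulation_zscore(c(1, 1), c(1, 1)), "undefined")
  expect_equal(z0, 0)
})

test_that("z-score rises with injected gain and nulls under shuffling", {
  set.seed(31)
  zs <- replicate(40, {
    rest <- rpois(40, 1) / 0.1
    act1 <- rpois(10, 1) / 0.1
    act2 <- rpois(10, 2) / 0.1   # doubled rate
    c(modulation_zscore(act1, rest), modulation_zscore(act2, rest))
  })
  expect_gt(mean(zs[2, ] > zs[1, ]), 0.8)   # gain raises z
  # label shuffling drives the mean z to zero
  set.seed(32)
  z_null <- replicate(200, {
    pool <- rpois(50, 1.5) / 0.1
    pick <- sample(50, 10)
    modulation_zscore(pool[pick], pool[-pick])
  })
  expect_lt(abs(mean(z_null)), 0.1)
})

test_that("selectivity matrices partition channels and match brute force", {
  # all silent
  map0 <- data.frame(channel = rep(1:56, 2),
                     condition = rep(c("knee_flexion", "knee_extension"),
                                     each = 56),
                     joint = "knee",
                     direction = rep(c("flexion", "extension"), each = 56),
                     z = 0, significant = FALSE)
  sel0 <- selectivity_matrix(map0, 56)
  expect_equal(sel0$per_joint$silent, 100)
  # 14 flexion-only of 56 -> 25%
  map1 <- map0
  map1$significant[map1$direction == "flexion" & map1$channel <= 14] <- TRUE
  sel1 <- selectivity_matrix(map1, 56)
  expect_equal(sel1$per_joint$flexion_only, 25)
  expect_equal(sum(unlist(sel1$per_joint[, 2:5])), 100)
  # random maps vs exhaustive per-channel re-derivation
  set.seed(41)
  joints <- c("knee", "ankle", "toes")
  map2 <- expand.grid(channel = 1:56, joint = joints,
                      direction = c("flexion", "extension"),
                      stringsAsFactors = FALSE)
  map2$condition <- paste(map2$joint, map2$direction, sep = "_")
  map2$significant <- runif(nrow(map2)) < 0.3
  map2$z <- ifelse(map2$significant, 1, 0)
  sel2 <- selectivity_matrix(map2, 56)
  for (j in joints) {
    row <- sel2$per_joint[sel2$per_joint$joint == j, ]
    expect_equal(sum(unlist(row[, 2:5])), 100, tolerance = 1e-9)
    # brute force over channels
    cats <- table(factor(vapply(1:56, function(ch) {
      f <- any(map2$significant[map2$channel == ch & map2$joint == j &
                                  map2$direction == "flexion"])
      e <- any(map2$significant[map2$channel == ch & map2$joint == j &
                                  map2$direction == "extension"])
      if (f && e) "both" else if (f) "flexion_only"
      else if (e) "extension_only" else "silent"
    }, character(1)), c("flexion_only", "extension_only", "both",
                        "silent")))
    expect_equal(unname(unlist(row[, 2:5])),
                 unname(as.numeric(cats)) / 56 * 100)
  }
})

test_that("motor-sensory overlap tables are percentage partitions", {
  map <- expand.grid(channel = 1:56, joint = c("knee", "ankle", "toes"),
                     direction = "flexion", stringsAsFactors = FALSE)
  map$significant <- FALSE
  map$significant[map$joint == "knee" & map$channel <= 7] <- TRUE
  # identical 7-channel motor and sensory sets -> both = 12.5%
  sens <- rep("none", 56); sens[1:7] <- "knee_calf"
  ov <- motor_sensory_overlap(map, sens)
  knee <- ov[ov$joint == "knee", ]
  expect_equal(knee$both, 12.5)
  expect_equal(knee$motor_only, 0)
  # disjoint sets -> both = 0
  sens2 <- rep("none", 56); sens2[40:46] <- "knee_calf"
  ov2 <- motor_sensory_overlap(map, sens2)
  expect_equal(ov2[ov2$joint == "knee", "both"], 0)
  # CSV round trip of the sensory table feeds the same overlap
  p <- file.path(tempdir(), "sens.csv")
  write.csv(data.frame(channel = 1:7, region = "knee_calf"), p,
            row.names = FALSE)
  expect_equal(load_sensory_map(p, 56), sens)
  # every region row sums to 100
  set.seed(4)
  sens3 <- sample(c("knee_calf", "ankle_heel", "foot_toes", "none"), 56,
                  replace = TRUE)
  map$significant <- runif(nrow(map)) < 0.4
  ov3 <- motor_sensory_overlap(map, sens3)
  expect_equal(rowSums(ov3[, 3:6]), rep(100, 3), ignore_attr = TRUE)
})

test_that("Herdin distance obeys its analytic cases and symmetries", {
  set.seed(51)
  R1 <- crossprod(matrix(rnorm(25), 5))
  expect_equal(herdin_distance(R1, 3 * R1), 0, tolerance = 1e-12)
  expect_equal(herdin_distance(diag(c(1, 0)), diag(c(0, 1))), 1)
  # independent elementwise evaluation on random symmetric pairs
  for (i in 1:20) {
    A <- crossprod(matrix(rnorm(25), 5))
    B <- crossprod(matrix(rnorm(25), 5))
    tr <- 0
    for (r in 1:5) for (c_ in 1:5) tr <- tr + A[r, c_] * B[c_, r]
    d_ref <- 1 - tr / (sqrt(sum(A * A)) * sqrt(sum(B * B)))
    expect_equal(herdin_distance(A, B), min(max(d_ref, 0), 1),
                 tolerance = 1e-12)
    expect_equal(herdin_distance(A, B), herdin_distance(B, A),
                 tolerance = 1e-12)
    expect_equal(herdin_distance(2.5 * A, 0.3 * B),
                 herdin_distance(A, B), tolerance = 1e-10)
  }
  expect_error(herdin_distance(matrix(0, 2, 2), diag(2)), "zero-norm")
})

test_that("muscle similarity matches a hand-enumerated toy example", {
  joints <- c("knee", "ankle", "toes")
  map <- expand.grid(channel = 1:10, joint = joints,
                     direction = "flexion", stringsAsFactors = FALSE)
  map$significant <- FALSE
  map$significant[map$joint == "knee" & map$channel %in% 1:4] <- TRUE
  map$significant[map$joint == "ankle" & map$channel %in% 3:8] <- TRUE
  map$significant[map$joint == "toes" & map$channel %in% 7:10] <- TRUE
  muscles <- muscle_matrix()
  expect_equal(sum(muscles$group == "flexor"), 7)
  expect_equal(sum(muscles$group == "extensor"), 4)
  d <- muscle_similarity(map, muscles, "flexion")
  # hand computation: neural Jaccards {1:4},{3:8},{7:10}
  J <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  N <- matrix(c(1, J(1:4, 3:8), J(1:4, 7:10),
                J(1:4, 3:8), 1, J(3:8, 7:10),
                J(1:4, 7:10), J(3:8, 7:10), 1), 3, 3)
  fl <- muscles[muscles$group == "flexor", ]
  sets <- lapply(paste0(joints, "_flexion"),
                 function(cl) fl$muscle[fl[[cl]] == 1])
  M <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) M[i, j] <- J(sets[[i]], sets[[j]])
  expect_equal(d, herdin_distance(N, M), tolerance = 1e-12)
  # identical overlap structures: distance 0
  expect_equal(herdin_distance(N, N), 0, tolerance = 1e-12)
  # an empty neural set names the joint
  map$significant[map$joint == "toes"] <- FALSE
  expect_error(muscle_similarity(map, muscles, "flexion"), "toes")
})

test_that("Friedman test matches hand-computed ranks", {
  # identical columns: statistic 0, p = 1
  m <- matrix(rep(c(3, 1, 2, 5, 4), 3), nrow = 3, byrow = TRUE)
  ft <- rate_friedman(m)
  expect_equal(ft$statistic, 0)
  expect_equal(ft$p.value, 1)
  # 3 groups x 5 subjects toy table vs the rank-sum formula
  set.seed(61)
  g <- matrix(rnorm(15), nrow = 3)            # groups x subjects
  ranks <- apply(g, 2, rank)                  # within-subject ranks
  Rj <- rowSums(ranks)
  n <- 5; k <- 3
  stat <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  ft2 <- rate_friedman(g)
  expect_equal(ft2$statistic, stat, tolerance = 1e-10)
  expect_equal(ft2$df, k - 1)
  expect_equal(ft2$p.value, pchisq(stat, k - 1, lower.tail = FALSE),
               tolerance = 1e-10)
  # missing values are an error
  g[1, 1] <- NA
  expect_error(rate_friedman(g), "missing")
})

test_that("modulation map flags tuned channels on generated data", {
  tun <- matrix(1, 4, 1, dimnames = list(NULL, "ankle_flexion"))
  tun[1:2, 1] <- 5
  cfg <- gen_config(n_channels = 4, classes = "ankle_flexion", blocks = 1,
                    reps = 4, tuning = tun, seed = 8)
  gen <- generate_recording(cfg)
  filt <- preprocess_recording(gen$recording, "eng", notch = FALSE)
  map <- build_modulation_map(filt, gen$trials, k = 3.5)
  expect_true(all(map$significant[map$channel <= 2]))
  expect_false(any(map$significant[map$channel > 2]))
  expect_true(all(map$mean_action_hz[map$channel <= 2] >
                    map$mean_rest_hz[map$channel <= 2]))
})
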