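test_that("contributing factor matches its closed form and limits", {
  # neutral residue contributes nothing at any distance
  expect_equal(contributing_factor(1.0, 7, 0.05), 1.0)
  # self term equals q
  expect_equal(contributing_factor(1.8, 0, 0.03164), 1.8)
  # direct evaluation 1 + 1/(1 + 9)
  expect_equal(contributing_factor(2.0, 3, 1.0), 1.1)
  # at the correlation length the factor is midway between q and 1
  expect_equal(contributing_factor(1.5, 0.03164^-0.5, 0.03164), 1.25)
  # decay toward 1, bounded between min(1, q) and max(1, q)
  s <- 1:50
  f_hi <- contributing_factor(1.7, s, 0.05)
  f_lo <- contributing_factor(0.6, s, 0.05)
  expect_true(all(diff(f_hi) < 0) && all(f_hi > 1) && all(f_hi < 1.7))
  expect_true(all(diff(f_lo) > 0) && all(f_lo < 1) && all(f_lo > 0.6))
  expect_error(contributing_factor(-1, 1, 0.05), "positive")
  expect_error(contributing_factor(1.2, 1, 0), "positive")
  expect_error(contributing_factor(1.2, -1, 0.05), "non-negative")
})

test_that("midpoint identity holds for random q", {
  set.seed(42)
  for (i in 1:25) {
    q <- runif(1, 0.3, 3)
    b <- runif(1, 1e-3, 1)
    expect_equal(contributing_factor(q, sqrt(1 / b), b), (q + 1) / 2)
  }
})

test_that("correlation length is b^(-1/2) with the self-only limit at 0", {
  expect_equal(round(correlation_length(3.164e-2), 1), 5.6)
  expect_equal(correlation_length(1), 1)
  expect_equal(correlation_length(0.04), 5)
  expect_equal(correlation_length(Inf), 0)
  expect_error(correlation_length(-1), "positive")
})

test_that("unscaled prediction matches hand-computed products", {
  # all factors 1 under the flat model
  expect_equal(predict_r2_unscaled(strrep("ACDY", 6), flat_params()),
               rep(1, 24))
  # single residue: only the self factor
  qv <- setNames(rep(1, 20), AA)
  qv["A"] <- 1.7
  expect_equal(predict_r2_unscaled("A", model_params(qv, 0.1)), 1.7)
  # AAA with q_A = 2, b = 1: position 1 = 2 * 1.5 * 1.2, center symmetric
  expect_equal(predict_r2_unscaled("AAA", spiked_params("A", 2, 1)),
               c(3.6, 4.5, 3.6))
})

test_that("vectorized prediction agrees with the brute-force oracle", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(1:8, 1)
    sq <- generate_sequence(n)
    p <- random_params()
    expect_equal(predict_r2_unscaled(sq, p), oracle_predict(sq, p),
                 tolerance = 1e-12)
  }
})

test_that("profiles show terminal falloff and mirror symmetry", {
  p <- spiked_params("G", 1.6, 0.05)
  prof <- predict_r2_unscaled(strrep("G", 41), p)
  mid <- 21
  expect_true(all(diff(prof[1:mid]) > 0))       # rises from the N-terminus
  expect_equal(prof, rev(prof))                 # palindrome symmetry
  expect_true(all(prof <= 1.6^41))
})

test_that("monotonicity: raising one q never lowers any value; large b moves toward self factors", {
  set.seed(5)
  sq <- generate_sequence(30)
  p1 <- random_params(b = 0.05)
  q2 <- p1$q
  q2["R"] <- q2["R"] + 0.4
  p2 <- model_params(q2, p1$b)
  expect_true(all(predict_r2_unscaled(sq, p2) >= predict_r2_unscaled(sq, p1)))
  # as b grows, every value approaches q at that position
  aa <- strsplit(sq, "")[[1]]
  pbig <- model_params(p1$q, 1e8)
  expect_equal(predict_r2_unscaled(sq, pbig), unname(p1$q[aa]),
               tolerance = 1e-6)
  expect_equal(predict_r2_unscaled(sq, model_params(p1$q, Inf)),
               unname(p1$q[aa]))
})

test_that("scaled prediction is linear in the scale and flags Pro", {
  p <- flat_params()
  prof <- predict_r2(strrep("AP", 5), p, scale = 3)
  expect_equal(prof$values, rep(3, 10))
  expect_equal(prof$mask, rep(c(TRUE, FALSE), 5))
  prof2 <- predict_r2(strrep("AP", 5), p, scale = 6)
  expect_equal(prof2$values, 2 * prof$values)
  expect_error(predict_r2("AAA", p, scale = 0), "positive")
})

test_that("gaussian kernel is available and decays faster than the lorentzian", {
  s <- 1:20
  fl <- contributing_factor(1.5, s, 0.05, kernel = "lorentzian")
  fg <- contributing_factor(1.5, s, 0.05, kernel = "gaussian")
  expect_equal(contributing_factor(1.5, 0, 0.05, kernel = "gaussian"), 1.5)
  expect_true(all(fg <= fl))
  qv <- setNames(runif(20, 0.8, 1.3), AA)
  pg <- model_params(qv, 0.1, kernel = "gaussian")
  expect_true(all(predict_r2_unscaled("ACDEFGHIKLMNQRSTVWY", pg) > 0))
})

test_that("sequence resolution enforces the alphabet with optional aliases", {
  expect_error(predict_r2_unscaled("ACX", flat_params()), "X")
  expect_error(resolve_sequence("ACB"), "position")
  # chemically modified residues can be remapped, e.g. methyl-Cys as Ala
  expect_equal(resolve_sequence("ACC", alias = c(C = "A")),
               c("A", "A", "A"))
  expect_error(resolve_sequence("AXC", alias = c(X = "A")), "X")
  p <- spiked_params("A", 1.5, 0.1)
  expect_equal(predict_r2_unscaled("CC", p, alias = c(C = "A")),
               predict_r2_unscaled("AA", p))
})

test_that("model parameter validation rejects bad inputs", {
  qv <- setNames(rep(1, 20), AA)
  expect_error(model_params(qv[-1], 0.1), "missing")
  expect_error(model_params(c(qv, Z = 1), 0.1), "amino acid")
  qv2 <- qv
  qv2["W"] <- 0
  expect_error(model_params(qv2, 0.1), "positive")
  expect_error(model_params(qv, -0.1), "positive")
  expect_silent(model_params(qv, Inf))  # self-only limit is legal
})

test_that("helix segment finding applies cutoff and length threshold", {
  expect_equal(nrow(find_helix_segments(rep(0, 50))), 0)
  # exactly 12 consecutive qualifying positions: boundary case survives
  s <- rep(0, 40)
  s[10:21] <- 0.995
  seg <- find_helix_segments(s)
  expect_equal(seg, data.frame(start = 10L, end = 21L))
  # 11 positions at 1.0 do not qualify
  s11 <- rep(0, 40)
  s11[10:20] <- 1.0
  expect_equal(nrow(find_helix_segments(s11)), 0)
  # a below-cutoff score splits a run; both halves requalify only if long
  s2 <- rep(1, 30)
  s2[15] <- 0.98
  expect_equal(find_helix_segments(s2),
               data.frame(start = c(1L, 16L), end = c(14L, 30L)))
  s2[4] <- 0.98  # leading fragment of 3 now drops out
  expect_equal(find_helix_segments(s2)$start, 16L)
  expect_error(find_helix_segments(c(0.5, 1.2)), "0, 1")
})

test_that("helix boost multiplies by 1 + alpha * pHlx inside segments only", {
  prof <- r2_profile(rep(2, 40))
  s <- rep(0, 40)
  s[5:20] <- 1.0
  seg <- find_helix_segments(s)
  boosted <- apply_helix_boost(prof, s, seg, alpha = 0.5)
  expect_equal(boosted$values[5:20], rep(3, 16))    # exactly x1.5
  expect_equal(boosted$values[-(5:20)], rep(2, 24)) # untouched outside
  # alpha = 0 and empty segments are identities
  expect_equal(apply_helix_boost(prof, s, seg, alpha = 0)$values, prof$values)
  none <- find_helix_segments(rep(0.9, 40))
  expect_equal(apply_helix_boost(prof, rep(0.9, 40), none)$values,
               prof$values)
  # per-residue scores modulate the boost inside a segment
  s3 <- rep(0, 40)
  s3[5:20] <- seq(0.99, 1.0, length.out = 16)
  seg3 <- find_helix_segments(s3)
  b3 <- apply_helix_boost(prof, s3, seg3)
  expect_equal(b3$values[5:20], 2 * (1 + 0.5 * s3[5:20]))
  expect_error(apply_helix_boost(prof, s, data.frame(start = 1, end = 99)),
               "range")
})
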