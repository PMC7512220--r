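test_that("identical groups give p = 1, zero effect, unchanged direction", {
  v <- matrix(rep(c(5, 7), each = 6), 2, byrow = TRUE,
              dimnames = list(c("pA", "pB"),
                              make_samples(3, 3)$sample_id))
  de <- t_test_protein(averaged_matrix(v), make_samples(3, 3))
  expect_equal(de$p_value, c(1, 1))
  expect_equal(de$log10_fc, c(0, 0))
  expect_equal(de$fold_change, c(1, 1))
  expect_true(all(de$direction == "unchanged"))
})

test_that("the pooled t matches stats::t.test on hand-worked vectors", {
  case <- c(10, 12, 11); control <- c(5, 6, 4)
  v <- rbind(pX = c(case, control))
  colnames(v) <- make_samples(3, 3)$sample_id
  s <- make_samples(3, 3)

  # untransformed scale against the textbook pooled-variance computation
  de_raw <- t_test_protein(averaged_matrix(v), s, log_transform = FALSE)
  ref <- t.test(case, control, var.equal = TRUE)
  expect_equal(de_raw$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(de_raw$log10_fc, log10(mean(case) / mean(control)),
               tolerance = 1e-12)

  # default log10 scale against the same oracle on transformed data
  de_log <- t_test_protein(averaged_matrix(v), s)
  ref_log <- t.test(log10(case), log10(control), var.equal = TRUE)
  expect_equal(de_log$p_value, ref_log$p.value, tolerance = 1e-12)

  # Welch variant
  de_w <- t_test_protein(averaged_matrix(v), s, log_transform = FALSE,
                         var_equal = FALSE)
  ref_w <- t.test(case, control)
  expect_equal(de_w$p_value, ref_w$p.value, tolerance = 1e-12)
})

test_that("the vectorized test agrees with per-protein t.test on a cohort", {
  co <- small_cohort(seed = 13L, n_proteins = 40L, n_de = 10L)
  m <- quantify_quiet(co)
  de <- t_test_protein(m$averaged, co$samples)
  grp <- co$samples$group[match(colnames(m$averaged$values),
                                co$samples$sample_id)]
  for (i in c(1L, 7L, 23L, 40L)) {
    x <- log10(m$averaged$values[i, ])
    ref <- t.test(x[grp == "case"], x[grp == "control"],
                  var.equal = TRUE)
    expect_equal(de$p_value[i], ref$p.value, tolerance = 1e-10)
  }
  expect_equal(de$q_value, p.adjust(de$p_value, "BH"))
})

test_that("exchanging group labels keeps p and flips the effect sign", {
  co <- small_cohort(seed = 17L, n_proteins = 30L, n_de = 6L)
  m <- quantify_quiet(co)
  de1 <- t_test_protein(m$averaged, co$samples)
  flipped <- co$samples
  flipped$group <- ifelse(flipped$group == "case", "control", "case")
  de2 <- t_test_protein(m$averaged, flipped)
  expect_equal(de1$p_value, de2$p_value, tolerance = 1e-12)
  expect_equal(de1$log10_fc, -de2$log10_fc, tolerance = 1e-12)
})

test_that("filter grammar retains by strict gates and sets direction", {
  recs <- data.frame(
    protein_id = c("a", "b", "c", "d"),
    p_value = c(0.00019, 0.0095, 0.011, 0.002),
    log10_fc = c(0.21, 0.29, 0.5, -0.35),
    fold_change = 10^c(0.21, 0.29, 0.5, -0.35),
    direction = "unchanged", stringsAsFactors = FALSE)
  out <- apply_filter(recs, primary_filter())
  # p = 0.011 exceeds the gate and is dropped; the rest are retained
  expect_identical(out$protein_id, c("a", "b", "d"))
  expect_identical(out$direction, c("increased", "increased", "decreased"))
  # idempotent
  expect_identical(apply_filter(out, primary_filter()), out)
  # effect gate: |lfc| below 0.2 is dropped regardless of p
  recs2 <- data.frame(protein_id = "e", p_value = 1e-6, log10_fc = 0.1,
                      fold_change = 10^0.1, direction = "unchanged")
  expect_equal(nrow(apply_filter(recs2, primary_filter())), 0L)
})

test_that("fold-change-expressed filters gate on the bounds", {
  recs <- data.frame(protein_id = c("a", "b", "c", "d"),
                     p_value = c(0.02, 0.04, 0.04, 0.06),
                     fold_change = c(1.5, 0.6, 1.1, 2.0),
                     direction = "unchanged", stringsAsFactors = FALSE)
  out <- apply_filter(recs, relaxed_filter())
  expect_identical(out$protein_id, c("a", "b"))
  expect_identical(out$direction, c("increased", "decreased"))
})

test_that("filter_spec validates its grammar", {
  expect_error(filter_spec(0.01), "exactly one")
  expect_error(filter_spec(0.01, lfc_min_abs = 0.2,
                           fc_bounds = c(1.3, 0.75)), "exactly one")
  expect_error(filter_spec(0, lfc_min_abs = 0.2), "p_max")
  expect_error(filter_spec(0.05, fc_bounds = c(0.75, 1.3)), "fc_bounds")
})

test_that("type-I error is calibrated on a null cohort", {
  co <- small_cohort(seed = 23L, n_proteins = 1500L, n_de = 0L)
  m <- quantify_quiet(co)
  de <- t_test_protein(m$averaged, co$samples)
  alpha <- 0.05
  frac <- mean(de$p_value < alpha)
  se <- sqrt(alpha * (1 - alpha) / nrow(de))
  expect_lt(abs(frac - alpha), 3 * se)
})

test_that("power rises monotonically with the planted effect size", {
  power_at <- function(effect) {
    co <- small_cohort(seed = 29L, n_proteins = 120L, n_de = 40L,
                       effect = effect)
    m <- quantify_quiet(co)
    de <- t_test_protein(m$averaged, co$samples)
    hits <- apply_filter(de, primary_filter())$protein_id
    mean(co$truth$protein_id[co$truth$is_de] %in% hits)
  }
  p_grid <- vapply(c(0.1, 0.25, 0.4), power_at, numeric(1L))
  expect_true(all(diff(p_grid) > 0))
})

test_that("planted 0.4-unit effects mostly pass the primary filter", {
  co <- small_cohort(seed = 37L, n_proteins = 200L, n_de = 50L,
                     effect = 0.4, noise_cv = 0.2)
  m <- quantify_quiet(co)
  de <- t_test_protein(m$averaged, co$samples)
  hits <- apply_filter(de, primary_filter())$protein_id
  recovered <- mean(co$truth$protein_id[co$truth$is_de] %in% hits)
  expect_gt(recovered, 0.5)
})

test_that("report formatting mirrors published rounding", {
  recs <- data.frame(protein_id = "x", p_value = 0.00019123,
                     log10_fc = 0.2112, fold_change = 1.6266,
                     direction = "increased", q_value = 0.04567)
  out <- format_differential(recs)
  expect_equal(out$p_value, 0.00019)
  expect_equal(out$log10_fc, 0.21)
  expect_equal(out$fold_change, 1.63)
})
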