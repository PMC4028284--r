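test_that("exclude_regions removes region and sex-chromosome variants, inclusive bounds", {
  v <- data.frame(
    id = c("in_mhc", "at_start", "before_start", "at_end", "after_end", "x_snp", "ok"),
    chrom = c("6", "6", "6", "6", "6", "X", "1"),
    pos = c(30000000L, 29624809L, 29624808L, 33160245L, 33160246L, 5L, 100L))
  out <- exclude_regions(v, mhc_region(), drop_sex = TRUE)
  expect_setequal(out$id, c("before_start", "after_end", "ok"))

  # empty region list, drop_sex = FALSE: identity
  expect_identical(exclude_regions(v, NULL, drop_sex = FALSE), v)

  # chr-prefixed names accepted; unknown chromosome rejected by record
  v2 <- data.frame(id = "a", chrom = "chr6", pos = 30000000L)
  expect_equal(nrow(exclude_regions(v2, mhc_region())), 0L)
  expect_error(exclude_regions(data.frame(id = "weird", chrom = "chr23", pos = 1L)),
               "weird")
})

test_that("label_hits applies tiers, universe restriction, dedup and p validation", {
  catalog <- data.frame(
    id = c("s1", "s2", "s3", "s2", "s4", "s5"),
    p_value = c("3e-9", "2e-6", "0.5", "4e-8", "1e-9", "not_a_p"),
    phenotype = c("t1", "t1", "t1", "t2", "t2", "t1"))
  universe <- c("s1", "s2", "s3", "s5")

  expect_warning(strong <- label_hits(catalog, universe, "strong"), "malformed")
  # s2's min reported p (4e-8) governs its tier; s4 is not in the universe
  expect_setequal(strong, c("s1", "s2"))
  weak <- suppressWarnings(label_hits(catalog, universe, "weak"))
  expect_setequal(weak, c("s1", "s2"))

  # phenotype filter sees only that phenotype's rows
  t2 <- suppressWarnings(label_hits(catalog, universe, "weak", phenotype = "t2"))
  expect_setequal(t2, "s2")
})

test_that("label_hits thresholds are strict", {
  cat_at <- data.frame(id = c("a", "b"), p_value = c(1e-5, 5e-8))
  # p exactly at a tier cutoff is excluded from that tier
  expect_setequal(label_hits(cat_at, c("a", "b"), "weak"), "b")
  expect_length(label_hits(cat_at, c("a", "b"), "strong"), 0)
  cat_below <- data.frame(id = c("a", "b"), p_value = c(0.99e-5, 4.9e-8))
  expect_setequal(label_hits(cat_below, c("a", "b"), "weak"), c("a", "b"))
  expect_setequal(label_hits(cat_below, c("a", "b"), "strong"), "b")
})

test_that("define_nonhits excludes hits and their LD partners, r2 inclusive at threshold", {
  pm <- proxy_map(data.frame(id_a = c("A", "A"), id_b = c("B", "D"),
                             r2 = c(0.9, 0.79)), r2_threshold = 0.5)
  expect_setequal(define_nonhits(c("A", "B", "C"), "A", pm, 0.8), "C")
  # r2 = 0.79 below threshold: D stays a non-hit
  expect_setequal(define_nonhits(c("A", "B", "C", "D"), "A", pm, 0.8), c("C", "D"))
  # boundary: r2 exactly at threshold is excluded
  pm2 <- proxy_map(data.frame(id_a = "A", id_b = "B", r2 = 0.8), 0.5)
  expect_setequal(define_nonhits(c("A", "B", "C"), "A", pm2, 0.8), "C")
  # no hits: everything is a non-hit
  expect_setequal(define_nonhits(c("A", "B"), character(), pm, 0.8), c("A", "B"))
})

test_that("hit_labeling partitions the universe exactly", {
  set.seed(11)
  ids <- sprintf("v%03d", 1:200)
  pairs <- data.frame(id_a = sample(ids, 80, replace = TRUE),
                      id_b = sample(ids, 80, replace = TRUE),
                      r2 = runif(80, 0.5, 1))
  pm <- proxy_map(pairs, r2_threshold = 0.8)
  hits <- sample(ids, 20)
  lab <- hit_labeling(ids, hits, pm)
  expect_length(intersect(lab$hit_ids, lab$nonhit_ids), 0)
  expect_length(intersect(lab$hit_ids, lab$ld_excluded_ids), 0)
  expect_equal(length(lab$hit_ids) + length(lab$nonhit_ids) +
                 length(lab$ld_excluded_ids), length(ids))
  # no non-hit is an LD partner of a hit
  expect_length(intersect(lab$nonhit_ids, ld_partners(pm, lab$hit_ids)), 0)
})

test_that("propagate_annotations takes the max over self and proxies", {
  vals <- rbind(idx1 = c(0, 0.4), idx2 = c(1, 0), px1 = c(1, 0.1), px2 = c(0, 1.3))
  colnames(vals) <- c("b", "q")
  am <- annotation_matrix(vals, feature_defs(c("b", "q"), c("binary", "quantitative")))
  pm <- proxy_map(data.frame(id_a = c("idx1", "idx1"), id_b = c("px1", "px2"),
                             r2 = c(0.9, 0.85)))
  out <- propagate_annotations(am, pm, index_ids = c("idx1", "idx2"))
  expect_equal(rownames(out$values), c("idx1", "idx2"))
  expect_equal(unname(out$values["idx1", ]), c(1, 1.3))  # binary 0 -> 1, quant max
  expect_equal(unname(out$values["idx2", ]), c(1, 0))    # no proxies: unchanged

  # missing proxy rows are all-zero, with a log message
  pm2 <- proxy_map(data.frame(id_a = "idx2", id_b = "ghost", r2 = 0.9))
  expect_message(out2 <- propagate_annotations(am, pm2, index_ids = "idx2"),
                 "absent")
  expect_equal(unname(out2$values["idx2", ]), c(1, 0))
})

test_that("propagation is idempotent, monotone, and commutes with clumping", {
  cfg <- sim_config(n_variants = 300, proxies_per_variant = 3, seed = 5)
  sim <- simulate_annotations(cfg)
  pm <- simulate_ld_proxies(cfg, sim$truth$id)
  # satellite proxies carry annotations: build an extended matrix
  sat <- ld_partners(pm, sim$truth$id)
  set.seed(6)
  sat_vals <- matrix(rbinom(length(sat) * ncol(sim$matrix$values), 1, 0.3),
                     nrow = length(sat), dimnames = list(sat, NULL))
  sat_vals[, sim$matrix$features$mode == "quantitative"] <-
    sat_vals[, sim$matrix$features$mode == "quantitative"] * 0.7
  colnames(sat_vals) <- sim$matrix$features$name
  ext <- annotation_matrix(rbind(sim$matrix$values, sat_vals), sim$matrix$features)

  once <- propagate_annotations(ext, pm, index_ids = sim$truth$id)
  twice <- propagate_annotations(once, pm, index_ids = sim$truth$id)
  expect_equal(twice$values, once$values)
  # never decreases any value
  expect_true(all(once$values >= sim$matrix$values))

  # propagate-then-clump == clump-then-propagate (both max reductions)
  groups <- ifelse(sim$matrix$features$mode == "binary", "grp", NA_character_)
  ext_g <- annotation_matrix(ext$values,
                             feature_defs(ext$features$name, ext$features$mode, groups))
  a <- clump_features(propagate_annotations(ext_g, pm, index_ids = sim$truth$id))
  b <- propagate_annotations(clump_features(ext_g), pm, index_ids = sim$truth$id)
  expect_equal(a$values, b$values)
})

test_that("clump_features collapses groups by max and passes quantitative through", {
  vals <- cbind(tf1 = c(1, 0, 0), tf2 = c(0, 0, 0), tf3 = c(0, 0, 1),
                eq1 = c(0, 1, 0), eq2 = c(0, 1, 0), cons = c(0.5, 0, 1.2))
  rownames(vals) <- c("v1", "v2", "v3")
  am <- annotation_matrix(vals, feature_defs(
    colnames(vals),
    c(rep("binary", 5), "quantitative"),
    c("any_tf", "any_tf", "any_tf", "any_eqtl", "any_eqtl", NA)))
  out <- clump_features(am)
  expect_equal(colnames(out$values), c("any_tf", "any_eqtl", "cons"))
  expect_equal(unname(out$values[, "any_tf"]), c(1, 0, 1))
  expect_equal(unname(out$values[, "any_eqtl"]), c(0, 1, 0))
  expect_equal(unname(out$values[, "cons"]), c(0.5, 0, 1.2))

  qvals <- cbind(a = c(0, 1), q = c(0.1, 0))
  rownames(qvals) <- c("v1", "v2")
  m <- annotation_matrix(qvals, feature_defs(c("a", "q"),
                                             c("binary", "quantitative")))
  m$features$clump_group <- "g"  # bypass constructor check: hit the op's own
  expect_error(clump_features(m), "quantitative")
})

test_that("track overlap uses BED half-open convention converted to 1-based", {
  bed <- tempfile(fileext = ".bed")
  writeLines("1\t10\t20", bed)  # covers 1-based positions 11..20
  track <- read_bed(bed)
  v <- data.frame(id = c("a", "b", "c", "d"), chrom = "1",
                  pos = c(10L, 11L, 20L, 21L))
  am <- build_annotation_matrix(v, list(feat = track))
  expect_equal(unname(am$values[, 1]), c(0, 1, 1, 0))
})

test_that("quantitative tracks average scores over overlapping blocks", {
  gr <- GenomicRanges::GRanges(c("1", "1"),
                               IRanges::IRanges(c(5, 8), c(10, 12)))
  gr$score <- c(1, 2)
  v <- data.frame(id = c("a", "b", "c"), chrom = "1", pos = c(9L, 6L, 20L))
  am <- build_annotation_matrix(v, list(cons = gr))
  expect_equal(unname(am$values[, 1]), c(1.5, 1, 0))
  expect_equal(am$features$mode, "quantitative")
})
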