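test_that("the four reconcilable allele configurations orient correctly", {
  ex <- assoc_row("rs1", "A", "G", beta = 0.02)
  cases <- list(
    list(ea = "A", oa = "G", flip = FALSE),   # identical
    list(ea = "G", oa = "A", flip = TRUE),    # swapped
    list(ea = "T", oa = "C", flip = FALSE),   # strand complement
    list(ea = "C", oa = "T", flip = TRUE))    # complement + swapped
  for (cs in cases) {
    out <- assoc_row("rs1", cs$ea, cs$oa, beta = 0.01, se = 0.004)
    h <- harmonize_pair(ex, out)
    expect_equal(h$variant$flipped, cs$flip)
    expect_equal(h$variant$beta_y, if (cs$flip) -0.01 else 0.01)
    expect_equal(h$variant$beta_x, 0.02)
  }
})

test_that("irreconcilable alleles and zero exposure effects are dropped", {
  ex <- assoc_row("rs1", "A", "G")
  expect_equal(harmonize_pair(ex, assoc_row("rs1", "A", "C"))$drop_reason,
               "allele-mismatch")
  expect_equal(harmonize_pair(ex, assoc_row("rs1", "A", "T"))$drop_reason,
               "allele-mismatch")   # palindromic vs non-palindromic
  expect_equal(
    harmonize_pair(assoc_row("rs1", beta = 0), assoc_row("rs1"))$drop_reason,
    "weak-zero exposure effect")
  expect_error(harmonize_pair(assoc_row("rs1"), assoc_row("rs2")),
               "rsid mismatch")
})

test_that("palindromic variants follow the policy table", {
  pal <- function(fx, fy, ea = "A", oa = "T", yea = ea, yoa = oa) {
    list(ex = assoc_row("rs1", ea, oa, beta = 0.02, eaf = fx),
         out = assoc_row("rs1", yea, yoa, beta = 0.01, eaf = fy))
  }
  # brute-force enumeration of the eaf_infer policy over frequency cells:
  # rows are (fx, fy, stated-swap) -> expected outcome
  grid <- list(
    list(fx = 0.2, fy = 0.25, swap = FALSE, expect = "keep", flip = FALSE),
    list(fx = 0.2, fy = 0.80, swap = FALSE, expect = "keep", flip = TRUE),
    list(fx = 0.8, fy = 0.20, swap = FALSE, expect = "keep", flip = TRUE),
    # stated swapped, frequencies concordant once re-expressed -> same
    # strand, so the stated swap is a real swap
    list(fx = 0.2, fy = 0.75, swap = TRUE,  expect = "keep", flip = TRUE),
    # stated swapped but frequencies discordant -> opposite strand, the
    # stated "other" allele is the exposure's effect allele
    list(fx = 0.2, fy = 0.20, swap = TRUE,  expect = "keep", flip = FALSE),
    list(fx = 0.51, fy = 0.2, swap = FALSE, expect = "drop"),
    list(fx = 0.2,  fy = 0.5, swap = FALSE, expect = "drop"),
    list(fx = NA,   fy = 0.2, swap = FALSE, expect = "drop"))
  for (g in grid) {
    cs <- if (g$swap) pal(g$fx, g$fy, yea = "T", yoa = "A")
          else pal(g$fx, g$fy)
    h <- harmonize_pair(cs$ex, cs$out, palindrome_policy = "eaf_infer",
                        eaf_window = 0.08)
    if (g$expect == "drop") {
      expect_equal(h$drop_reason, "palindromic-ambiguous")
    } else {
      expect_equal(h$variant$flipped, g$flip)
    }
  }
  # fixed policies ignore frequencies
  cs <- pal(0.51, 0.49)
  expect_equal(harmonize_pair(cs$ex, cs$out, "drop")$drop_reason,
               "palindromic")
  expect_false(harmonize_pair(cs$ex, cs$out, "keep")$variant$flipped)
  cs2 <- pal(0.51, 0.49, yea = "T", yoa = "A")
  expect_true(harmonize_pair(cs2$ex, cs2$out, "keep")$variant$flipped)
})

test_that("every input variant lands in the panel or in dropped, once", {
  ex <- make_dataset(list(assoc_row("rs1", "A", "G"),
                          assoc_row("rs2", "C", "T"),
                          assoc_row("rs3", "A", "C")),
                     trait_type = "exposure")
  out <- make_dataset(list(assoc_row("rs1", "G", "A"),
                           assoc_row("rs2", "C", "A"),   # irreconcilable
                           assoc_row("rs4", "A", "C")))  # rs3 missing
  suppressMessages(p <- harmonize_panel(ex, out))
  expect_s3_class(p, "harmonized_panel")
  expect_equal(p$variants$rsid, "rs1")
  expect_true(p$variants$flipped)
  expect_setequal(c(p$variants$rsid, p$dropped$rsid), c("rs1", "rs2", "rs3"))
  expect_equal(sort(p$dropped$reason), sort(c("allele-mismatch", "missing")))
  out_none <- make_dataset(list(assoc_row("rs1", "A", "C")))
  expect_error(suppressMessages(harmonize_panel(ex, out_none)),
               "no instruments")
})

test_that("harmonization is involution-consistent", {
  study <- simulate_study(sim_config(n_variants = 60, swap_fraction = 0.3,
                                     complement_fraction = 0.2, seed = 5))
  p1 <- harmonize_panel(study$exposure, study$outcomes$GWAS)
  # re-express the harmonized panel as datasets and harmonize again
  ex2 <- study$exposure
  out2 <- make_dataset(lapply(seq_len(nrow(p1$variants)), function(i) {
    v <- p1$variants[i, ]
    e <- as.data.frame(ex2)[match(v$rsid, ex2$rsid), ]
    assoc_row(v$rsid, e$effect_allele, e$other_allele, beta = v$beta_y,
              se = v$se_y)
  }))
  p2 <- harmonize_panel(ex2, out2, rsids = p1$variants$rsid)
  expect_equal(p2$variants$beta_y, p1$variants$beta_y)
  expect_false(any(p2$variants$flipped))
})

test_that("generator orientation scrambling is recovered exactly", {
  study <- simulate_study(sim_config(n_variants = 200, swap_fraction = 0.1,
                                     complement_fraction = 0.1, seed = 9))
  p <- harmonize_panel(study$exposure, study$outcomes$GWAS)
  expect_equal(nrow(p$variants), 200L)
  truth <- study$truth
  # expected flip: outcome stated orientation differs from exposure's
  want <- xor(truth$datasets$GWAS$swapped, truth$variants$exposure_swapped)
  got <- p$variants$flipped[match(truth$variants$rsid, p$variants$rsid)]
  expect_equal(got, want)
  # harmonized outcome betas equal the analysis-orientation truth, re-signed
  # to the exposure's stated allele
  sgn <- ifelse(truth$variants$exposure_swapped, -1, 1)
  expect_equal(p$variants$beta_y[match(truth$variants$rsid, p$variants$rsid)],
               sgn * truth$datasets$GWAS$beta_y_true)
})

test_that("Wald ratios are invariant to the effect-allele choice", {
  study <- simulate_study(sim_config(n_variants = 40, seed = 3))
  base <- wald_ratio(harmonize_panel(study$exposure, study$outcomes$GWAS))
  for (rep_seed in 1:5) {
    set.seed(rep_seed)
    flip <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    ex <- as.data.frame(study$exposure)
    tmp <- ex$effect_allele[flip]
    ex$effect_allele[flip] <- ex$other_allele[flip]
    ex$other_allele[flip] <- tmp
    ex$beta[flip] <- -ex$beta[flip]
    ex$eaf[flip] <- 1 - ex$eaf[flip]
    ex <- summary_dataset(ex, label = "exposure", trait_type = "exposure")
    w <- wald_ratio(harmonize_panel(ex, study$outcomes$GWAS))
    expect_equal(w$theta[match(base$rsid, w$rsid)], base$theta,
                 tolerance = 1e-12)
    expect_equal(w$variance[match(base$rsid, w$rsid)], base$variance,
                 tolerance = 1e-12)
  }
})

test_that("panel TSV round trip preserves the exchange columns", {
  study <- simulate_study(sim_config(n_variants = 12, seed = 2))
  p <- harmonize_panel(study$exposure, study$outcomes$GWAS)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(p, path)
  p2 <- read_panel(path)
  expect_equal(p2$variants, p$variants, tolerance = 1e-12)
})
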