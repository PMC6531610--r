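test_that("the default family scenario reproduces the 38 / 4 cascade structure", {
  sc <- family_scenario()
  rep <- run_filter_cascade(sc$fam$variants, sc$cfg)
  stages <- rep$stages
  expect_identical(stages$stage,
                   c("quality", "rarity", "zygosity", "sharing", "locus",
                     "segregation", "control_absence"))
  # counts never increase along the cascade
  expect_true(all(stages$n_out <= stages$n_in))
  expect_true(all(stages$n_in[-1] == stages$n_out[-nrow(stages)]))
  # 38 disease-haplotype variants survive through segregation; the 4
  # family-unique ones survive control genotyping
  expect_identical(stages$n_out[stages$stage == "segregation"], 38L)
  expect_identical(stages$n_out[stages$stage == "control_absence"], 4L)
  truth4 <- sc$fam$truth$id[sc$fam$truth$class == "linked_unique"]
  expect_setequal(rep$final_ids, truth4)
  # survivors are nested along the cascade
  surv <- rep$survivors
  for (i in seq_along(surv)[-1]) {
    expect_true(all(surv[[i]] %in% surv[[i - 1]]))
  }
})

test_that("rarity requires the MAF to clear the threshold in every panel", {
  sc <- family_scenario()
  v <- sc$fam$variants[1, ]
  v$panel_freqs <- list(c(`1kg` = 0.02, inhouse = 0.001))
  rep <- run_filter_cascade(v, sc$cfg)
  expect_identical(rep$stages$n_out[rep$stages$stage == "rarity"], 0L)
  # exactly at the threshold is not rare (strict less-than)
  v$panel_freqs <- list(c(`1kg` = 0.01, inhouse = 0.001))
  rep2 <- run_filter_cascade(v, sc$cfg)
  expect_identical(rep2$stages$n_out[rep2$stages$stage == "rarity"], 0L)
})

test_that("empty input and unknown samples are handled per contract", {
  sc <- family_scenario()
  empty <- sc$fam$variants[0, ]
  rep <- run_filter_cascade(empty, sc$cfg)
  expect_true(all(rep$stages$n_in == 0L) && all(rep$stages$n_out == 0L))

  bad_cfg <- filter_config(sequenced_affecteds = "nobody",
                           pedigree = sc$cfg$pedigree)
  expect_error(run_filter_cascade(sc$fam$variants, bad_cfg), "missing from genotype")
})

test_that("missing genotypes fail sharing conservatively but not control absence", {
  sc <- family_scenario()
  v <- sc$fam$variants
  linked <- which(sc$fam$truth$class == "linked_unique")
  v[["III-1"]][linked[1]] <- "./."
  v[["CTRL01"]][linked[2]] <- "./."
  rep <- run_filter_cascade(v, sc$cfg)
  expect_identical(rep$stages$n_out[rep$stages$stage == "sharing"], 37L)
  expect_identical(length(rep$final_ids), 3L)
  expect_true(v$id[linked[2]] %in% rep$final_ids)
})

test_that("segregation classification follows carrier status", {
  ped <- default_pedigree()
  gts <- setNames(ifelse(ped$carries_disease_haplotype, "0/1", "0/0"),
                  ped$sample_id)
  expect_identical(check_segregation(gts, ped), "segregates")

  broken <- gts
  broken[["III-5"]] <- "0/0"  # a haplotype carrier without the variant
  expect_identical(check_segregation(broken, ped), "violates")

  leaked <- gts
  leaked[["III-2"]] <- "0/1"  # a non-carrier with the variant
  expect_identical(check_segregation(leaked, ped), "violates")

  sparse <- setNames(rep("./.", nrow(ped)), ped$sample_id)
  sparse[["III-1"]] <- "0/1"
  expect_identical(check_segregation(sparse, ped), "uninformative")
})

test_that("planted haplotype variants segregate; off-locus ones mostly do not", {
  sc <- family_scenario(seed = 12)
  v <- sc$fam$variants
  status <- vapply(seq_len(nrow(v)), function(i) {
    check_segregation(v[i, ], sc$fam$pedigree)
  }, "")
  linked <- sc$fam$truth$class != "offlocus"
  expect_true(all(status[linked] == "segregates"))
  # off-locus variants segregate only by chance
  expect_lt(mean(status[!linked] == "segregates"), 0.2)
})

test_that("permuting genotype-independent stages leaves the survivor set unchanged", {
  sc <- family_scenario(seed = 21)
  v <- sc$fam$variants
  cfg <- sc$cfg
  rep <- run_filter_cascade(v, cfg)
  # recompute the final set applying the same predicates in a different
  # order: locus and rarity first, then quality, then the genotype stages
  ids <- v$id
  in_locus <- (v$pos - 1) >= cfg$locus[[1]] & (v$pos - 1) < cfg$locus[[2]]
  rare <- vapply(v$panel_freqs, function(pf) all(pf < cfg$maf_threshold), logical(1))
  qual_ok <- v$qual >= cfg$min_quality
  aff <- sapply(cfg$sequenced_affecteds, function(s) v[[s]])
  shared <- apply(aff, 1, function(g) all(g %in% c("0/1", "1/0")))
  seg <- vapply(seq_len(nrow(v)), function(i) {
    check_segregation(v[i, ], cfg$pedigree) == "segregates"
  }, logical(1))
  ctrl <- sapply(cfg$control_samples, function(s) v[[s]])
  absent <- apply(ctrl, 1, function(g) all(g %in% c("0/0", "./.")))
  expect_setequal(rep$final_ids,
                  ids[in_locus & rare & qual_ok & shared & seg & absent])
})
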