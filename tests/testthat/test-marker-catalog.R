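makeDE <- function(feature, log2_fc, p_value, base_sen = 2000,
                   base_ctrl = 2000) {
  data.frame(feature = feature, log2_fc = log2_fc, p_value = p_value,
             adj_p = p.adjust(p_value, "BH"), base_sen = base_sen,
             base_ctrl = base_ctrl)
}

test_that("simpleDE matches hand computations and the t.test oracle", {
  v <- rbind(flat = rep(100, 6),
             up = c(1, 1, 1, 3, 3, 3) * 1000)
  v <- v + 0                       # numeric matrix, features x samples
  colnames(v) <- paste0("s", 1:6)
  se <- SenExperiment(v, cell_type = rep("A", 6), trigger = rep("CTIS", 6),
                      state = rep(c("control", "senescent"), each = 3))
  de <- simpleDE(se)
  # identical values in both arms: no signal
  expect_equal(de$log2_fc[de$feature == "flat"], 0)
  expect_equal(de$p_value[de$feature == "flat"], 1)
  # (3,3,3) vs (1,1,1) in thousands: pseudo-counted ratio log2(3001/1001)
  expect_equal(de$log2_fc[de$feature == "up"], log2(3001 / 1001),
               tolerance = 1e-12)

  # antisymmetry under swapping arm labels
  se2 <- se
  colData(se2)$state <- ifelse(colData(se)$state == "control",
                               "senescent", "control")
  de2 <- simpleDE(se2)
  expect_equal(de2$log2_fc, -de$log2_fc)
  expect_equal(de2$p_value, de$p_value)

  # vectorized Welch p agrees with stats::t.test on jittered rows
  withr::with_seed(42, {
    vj <- matrix(rlnorm(10 * 6, log(500), 0.4), 10, 6,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
    sej <- SenExperiment(vj, rep("A", 6), rep("CTIS", 6),
                         rep(c("control", "senescent"), each = 3))
    dej <- simpleDE(sej)
    pref <- sapply(1:10, function(i)
      t.test(log2(vj[i, 4:6] + 1), log2(vj[i, 1:3] + 1))$p.value)
    expect_equal(dej$p_value, pref, tolerance = 1e-10)
  })

  # an arm with < 2 samples errors, naming the arm
  expect_error(simpleDE(se[, c(1, 2, 4)]), "senescent arm")
})

test_that("simpleDE drops protein features with >50% missing in an arm", {
  v <- matrix(rlnorm(3 * 6, log(1e6), 0.3), 3, 6,
              dimnames = list(c("ok", "holey", "gone"), paste0("s", 1:6)))
  v["holey", 1] <- NA                # 1/3 missing in control: kept
  v["gone", 1:2] <- NA               # 2/3 missing in control: dropped
  se <- SenExperiment(v, rep("A", 6), rep("CTIS", 6),
                      rep(c("control", "senescent"), each = 3),
                      modality = "protein")
  de <- simpleDE(se)
  expect_setequal(de$feature, c("ok", "holey"))
})

test_that("marker calling applies fold, significance and abundance rules", {
  de <- makeDE(c("a", "b", "c", "d", "e"),
               log2_fc = c(1.0, 0.5, -2.0, -1.0, 1.0),
               p_value = c(0.01, 0.001, 0.2, 0.01, 0.01),
               base_sen = c(1500, 5000, 5000, 100, 500),
               base_ctrl = c(500, 5000, 5000, 1500, 100))
  mk <- callModelMarkers(de, markerThresholds(), "RNA", "CTA", "CTIS")
  expect_identical(markerFeatures(mk$up), "a")     # passes all three rules
  expect_false("b" %in% markerFeatures(mk$up))     # below fold threshold
  expect_false("c" %in% markerFeatures(mk$down))   # p above 0.05
  expect_identical(markerFeatures(mk$down), "d")   # abundant in control arm
  expect_false("e" %in% markerFeatures(mk$up))     # below expression floor

  # protein has no abundance floor
  mkp <- callModelMarkers(de, markerThresholds(), "protein")
  expect_setequal(markerFeatures(mkp$up), c("a", "e"))

  # literal floor mode requires down markers *below* the floor in control
  mkl <- callModelMarkers(de, markerThresholds(floor_mode = "literal"), "RNA")
  expect_identical(markerFeatures(mkl$down), character(0))

  expect_error(callModelMarkers(de, markerThresholds(), "ATAC"),
               "unknown modality")
})

test_that("marker calling is order-independent and directions are exclusive", {
  withr::with_seed(7, {
    for (i in 1:5) {
      de <- makeDE(sprintf("g%02d", 1:40), log2_fc = rnorm(40, 0, 1.2),
                   p_value = runif(40)^2, base_sen = rlnorm(40, log(2000), 1),
                   base_ctrl = rlnorm(40, log(2000), 1))
      mk <- callModelMarkers(de, markerThresholds(), "RNA")
      shuf <- callModelMarkers(de[sample(nrow(de)), ], markerThresholds(), "RNA")
      expect_setequal(markerFeatures(mk$up), markerFeatures(shuf$up))
      expect_setequal(markerFeatures(mk$down), markerFeatures(shuf$down))
      expect_length(intersect(markerFeatures(mk$up), markerFeatures(mk$down)), 0)
    }
  })
})

test_that("trigger intersection behaves as set intersection with checks", {
  s1 <- MarkerSet("CTA", "CTIS", "RNA", "up", c("A", "B", "C"))
  s2 <- MarkerSet("CTA", "IRIS", "RNA", "up", c("A", "B"))
  s3 <- MarkerSet("CTA", "OSIS", "RNA", "up", c("D"))
  expect_setequal(markerFeatures(intersectTriggers(list(s1, s2))), c("A", "B"))
  expect_identical(intersectTriggers(list(s1))@features, s1@features)
  expect_identical(intersectTriggers(list(s1))@trigger, "ALL")
  expect_length(markerFeatures(intersectTriggers(list(s1, s3))), 0)
  expect_error(intersectTriggers(list(s1, MarkerSet("CTB", "CTIS", "RNA",
                                                    "up", "A"))),
               "mixed cell types")
  # monotone non-increasing as paradigms accumulate
  sets <- list(s1, s2, MarkerSet("CTA", "OIS", "RNA", "up", c("A", "C")))
  sizes <- sapply(seq_along(sets), function(k)
    length(markerFeatures(intersectTriggers(sets[seq_len(k)]))))
  expect_true(all(diff(sizes) <= 0))
})

test_that("sharing table counts cell types and feeds the ranked top list", {
  sets <- list(MarkerSet("CT1", "ALL", "RNA", "up", c("g1", "g2")),
               MarkerSet("CT2", "ALL", "RNA", "up", c("g1", "g3")),
               MarkerSet("CT3", "ALL", "RNA", "up", c("g1", "g2", "g3")),
               MarkerSet("CT4", "ALL", "RNA", "up", c("g1")),
               MarkerSet("CT5", "ALL", "RNA", "up", c("g1", "g2")))
  st <- sharingTable(sets)
  expect_identical(st$n_cell_types[st$feature == "g1"], 5L)
  expect_identical(st$n_cell_types[st$feature == "g2"], 3L)
  expect_false("absent" %in% st$feature)
  expect_error(sharingTable(c(sets, sets[1])), "duplicate cell-type keys")

  # sharing-count filter at the conventional cutoff of 4
  expect_setequal(topShared(st, k = 20, min_cell_types = 4), "g1")

  # tie-break by summed |log2FC|, then identifier
  st2 <- data.frame(feature = c("g1", "g2", "g3"),
                    n_cell_types = c(7L, 5L, 5L),
                    cell_types = "", direction = "up")
  eff <- c(g1 = 1, g2 = 9, g3 = 2)
  expect_identical(topShared(st2, k = 2, effect = eff), c("g1", "g2"))
  expect_identical(topShared(st2, k = 2), c("g1", "g2"))  # lexicographic
  expect_identical(topShared(st2, k = 10), c("g1", "g2", "g3"))
  expect_error(topShared(st2, k = 0), "k must be > 0")
  expect_identical(formals(topShared)$k, 20L)
})

test_that("cell-type marker ranking sums log2 fold changes across models", {
  de1 <- makeDE(c("g1", "g2"), c(1.0, 1.4), c(0.01, 0.01))
  de2 <- makeDE(c("g1", "g2"), c(2.0, 1.4), c(0.01, 0.01))
  mk <- MarkerSet("CTA", "ALL", "RNA", "up", c("g1", "g2"))
  r <- topCellTypeMarkers(list(de1, de2), mk)
  expect_identical(r$feature, c("g1", "g2"))     # 3.0 > 2.8
  expect_equal(r$sum_log2_fc, c(3.0, 2.8))

  r1 <- topCellTypeMarkers(list(de2), mk)
  expect_identical(r1$feature, c("g1", "g2"))    # single model: its ordering

  dn <- MarkerSet("CTA", "ALL", "RNA", "down", c("g1", "g2"))
  expect_identical(topCellTypeMarkers(list(de1), dn)$feature, c("g1", "g2"))

  expect_error(topCellTypeMarkers(list(makeDE("g1", 1, 0.01)), mk),
               "missing from DE table")
  expect_identical(nrow(topCellTypeMarkers(list(de1), mk, k = 1)), 1L)
})

test_that("modality overlap reports Jaccard and min-denominator percentages", {
  ov <- modalityOverlap(c("a", "b", "c", "d"), c("c", "d", "e", "f"))
  expect_equal(ov$jaccard_pct, 100 * 2 / 6, tolerance = 1e-12)
  expect_equal(ov$min_pct, 50)
  expect_setequal(ov$intersection, c("c", "d"))
  same <- modalityOverlap(c("x", "y"), c("x", "y"))
  expect_equal(c(same$jaccard_pct, same$min_pct), c(100, 100))
  disj <- modalityOverlap("x", "y")
  expect_equal(c(disj$jaccard_pct, disj$min_pct), c(0, 0))
  none <- modalityOverlap(character(), character())
  expect_equal(c(none$jaccard_pct, none$min_pct), c(0, 0))
})

test_that("ortholog expansion takes all mappings and reports unmapped input", {
  tbl <- data.frame(human = c("H1", "H1", "H2"),
                    mouse = c("m1", "m2", "m3"))
  expect_setequal(expandOrthologs("H1", tbl)$mouse, c("m1", "m2"))
  out <- expandOrthologs(c("H1", "H2"), tbl)
  expect_setequal(out$mouse, c("m1", "m2", "m3"))
  expect_length(out$unmapped, 0)
  miss <- expandOrthologs("H9", tbl)
  expect_length(miss$mouse, 0)
  expect_identical(miss$unmapped, "H9")
  expect_error(expandOrthologs("H1", data.frame(a = 1)), "columns")
})

test_that("expanded lists emit the shared-by-4 set and per-lineage top lists", {
  mk <- function(ct, tr, feats) MarkerSet(ct, tr, "RNA", "up", feats)
  model_sets <- list(
    mk("CT1", "CTIS", c("s4", "s6", "a")), mk("CT1", "IRIS", c("s4", "s6", "a")),
    mk("CT2", "CTIS", c("s4", "s6", "b")), mk("CT2", "IRIS", c("s4", "s6")),
    mk("CT3", "CTIS", c("s4", "s6")),
    mk("CT4", "CTIS", c("s4", "s6")),
    mk("CT5", "CTIS", c("s6")))
  out <- expandedLists(model_sets,
                       lineages = list(fib = c("CT1", "CT2")), top_n = 2)
  # s4 in exactly 4 cell types, s6 in 5: both pass the >= 4 cutoff
  expect_setequal(out$Allsenshared, c("s4", "s6"))
  # within the lineage s4 and s6 tie at 4 models: identifier breaks the tie
  expect_identical(out$fib, c("s4", "s6"))
  # a supplied effect ranking overrides the identifier tie-break
  out_eff <- expandedLists(model_sets, lineages = list(fib = c("CT1", "CT2")),
                           top_n = 2, effect = c(s4 = 0.6, s6 = 2.5))
  expect_identical(out_eff$fib, c("s6", "s4"))
  out2 <- expandedLists(model_sets, lineages = list(fib = c("CT1", "CT2")),
                        top_n = 500)
  expect_lte(length(out2$fib), 500)
  expect_true(all(c("a", "b") %in% out2$fib))
  expect_error(expandedLists(model_sets, lineages = list(x = "CT99")),
               "unknown cell types")
})

test_that("catalog recovers planted shared markers on a replicated corpus", {
  # replicates_per_arm = 8: prospective power analysis shows 3/arm gives only
  # ~0.3 per-model detection power at the default dispersion, far too little
  # for the trigger-intersection catalog; 8/arm gives ~0.93.
  stats <- sapply(1:5, function(s) {
    sim <- makeBulkDataset(bulkSimConfig(replicates_per_arm = 8, seed = s))
    se <- sim$rna
    cd <- as.data.frame(colData(se))
    models <- unique(cd[, c("cell_type", "trigger")])
    up_sets <- lapply(seq_len(nrow(models)), function(i) {
      de <- simpleDE(se, models$cell_type[i], models$trigger[i])
      callModelMarkers(de, markerThresholds(), "RNA",
                       models$cell_type[i], models$trigger[i])$up
    })
    ct_up <- lapply(split(up_sets, models$cell_type), intersectTriggers)
    st <- sharingTable(unname(ct_up))
    truth <- sim$truth$rna
    planted_all <- unlist(c(truth$planted_shared_up, truth$planted_shared_down,
                            truth$planted_type_specific))
    c(recovered = mean(truth$planted_shared_up %in%
                         st$feature[st$n_cell_types >= 7]),
      false_pos = mean(setdiff(rownames(se), planted_all) %in%
                         st$feature[st$n_cell_types >= 4]))
  })
  expect_gte(mean(stats["recovered", ]), 0.90)
  expect_lte(mean(stats["false_pos", ]), 0.01)
})
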