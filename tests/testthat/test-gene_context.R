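test_that("annotations load with validation and unknown-compound reporting", {
  toy <- toy_genome()
  lib <- toy_library()
  model <- load_annotations(toy$genes, toy$links, lib)
  expect_s3_class(model, "genome_model")
  expect_equal(nrow(model$genes), 6)
  # 1-based inclusive coordinates pass through unchanged
  expect_equal(model$genes$start[model$genes$gene_id == "tgt"], 10000L)
  expect_equal(model$genes$end[model$genes$gene_id == "tgt"], 11000L)

  bad_links <- rbind(toy$links,
                     data.frame(gene_id = "near", compound_id = "ghost",
                                role = "product"))
  expect_warning(m2 <- load_annotations(toy$genes, bad_links, lib), "ghost")
  expect_equal(m2$unknown_compounds, "ghost")

  dup <- rbind(toy$genes, toy$genes[1, ])
  expect_error(load_annotations(dup, toy$links), "duplicate")
  noc <- toy$genes
  noc$start[2] <- NA
  expect_error(load_annotations(noc, toy$links), "coordinates")
})

test_that("GFF3 gene features load into the same model", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\ttest\tgene\t10000\t11000\t.\t+\t.\tID=tgt",
    "c1\ttest\tgene\t12001\t12500\t.\t-\t.\tID=near"), gff)
  model <- load_annotations(gff, toy_genome()$links)
  expect_equal(sort(model$genes$gene_id), c("near", "tgt"))
  expect_equal(model$genes$start[model$genes$gene_id == "tgt"], 10000L)
})

test_that("neighbour search respects the inclusive gap threshold", {
  # gaps {0, 500, 1999, 2001} at threshold 2000 keep exactly three genes
  genes <- data.frame(
    gene_id = c("t", "g0", "g500", "g1999", "g2001"),
    contig = "c",
    start = c(5000L, 5500L, 6501L, 8000L, 8002L),
    end = c(6000L, 6400L, 6900L, 8400L, 8500L),
    strand = "+")
  genes$start[4] <- 8000L; genes$end[4] <- 8300L
  # gaps: g0 overlaps (0), g500: 6501-6000-1 = 500, g1999: 8000-6000-1 = 1999,
  # g2001: 8002-6000-1 = 2001
  model <- load_annotations(genes, data.frame(gene_id = character(0),
                                              compound_id = character(0),
                                              role = character(0)))
  nbh <- neighbors(model, "t", 2000L)
  expect_setequal(nbh$neighbors$gene_id, c("g0", "g500", "g1999"))

  # threshold zero keeps only overlapping/abutting genes
  nbh0 <- neighbors(model, "t", 0L)
  expect_equal(nbh0$neighbors$gene_id, "g0")

  expect_error(neighbors(model, "nope", 2000L), "unknown target")
})

test_that("neighbourhoods grow monotonically with the gap threshold", {
  w <- gen_world(world_config(seed = 13, n_genomes = 5))
  model <- w$genomes$model
  for (tid in w$genomes$targets) {
    prev <- character(0)
    for (gap in c(0L, 500L, 1500L, 2000L, 5000L)) {
      cur <- neighbors(model, tid, gap)$neighbors$gene_id
      expect_true(all(prev %in% cur), info = paste(tid, gap))
      prev <- cur
    }
  }
})

test_that("a target at the contig edge gets a one-sided neighbourhood", {
  genes <- data.frame(gene_id = c("t", "down"), contig = "c",
                      start = c(1L, 2000L), end = c(900L, 2900L), strand = "+")
  model <- load_annotations(genes, data.frame(gene_id = character(0),
                                              compound_id = character(0),
                                              role = character(0)))
  nbh <- neighbors(model, "t", 5000L)
  expect_equal(nbh$neighbors$side, "downstream")
  expect_true(nbh$neighbors$adjacent)
})

test_that("context candidates rank by similarity with product preference", {
  toy <- toy_genome()
  lib <- toy_library()
  model <- load_annotations(toy$genes, toy$links, lib)
  nbh <- neighbors(model, "tgt", 2000L)

  # single reference identical to a neighbour product
  pred <- context_candidates(nbh, model, lib, reference = "cpdA")
  expect_equal(pred$status, "ok")
  expect_equal(pred$candidates$compound_id[1], "cpdA")
  expect_equal(pred$candidates$ti[1], 1.0)

  # ties between a product and a substrate resolve product-first
  links_tie <- data.frame(gene_id = c("near", "near"),
                          compound_id = c("cpdA", "cpdA"),
                          role = c("substrate", "product"))
  model_tie <- load_annotations(toy$genes, links_tie, lib)
  nbh_tie <- neighbors(model_tie, "tgt", 2000L)
  pt <- context_candidates(nbh_tie, model_tie, lib, reference = "cpdA")
  expect_equal(pt$candidates$role[1], "product")

  # no annotated neighbour compounds -> explicit no-information status
  empty_links <- data.frame(gene_id = character(0), compound_id = character(0),
                            role = character(0))
  model_empty <- load_annotations(toy$genes, empty_links, lib)
  pe <- context_candidates(neighbors(model_empty, "tgt", 2000L),
                           model_empty, lib)
  expect_equal(pe$status, "no-information")
})

test_that("a near-identical neighbour product beats dissimilar decoys", {
  # operon logic: the planted product has TI ~0.7 to the target's known
  # substrate while decoys stay below 0.3
  target_fp <- c(rep(1, 10), rep(0, 10))
  product_fp <- c(rep(1, 8), 0, 0, 1, 1, rep(0, 8))   # TI = 8/12 ~ 0.67
  decoy_fp <- c(rep(0, 14), rep(1, 6))                 # TI vs target = 0
  decoy_fp2 <- c(rep(0, 10), rep(1, 4), rep(0, 6))     # also disjoint from target
  fps <- rbind(target_sub = target_fp, planted = product_fp,
               decoy1 = decoy_fp, decoy2 = decoy_fp2)
  lib <- compound_library(rownames(fps), fps)
  genes <- data.frame(gene_id = c("t", "prod", "d1"), contig = "c",
                      start = c(10000L, 8000L, 12000L),
                      end = c(11000L, 8900L, 12900L), strand = "+")
  links <- data.frame(gene_id = c("prod", "d1", "d1"),
                      compound_id = c("planted", "decoy1", "decoy2"),
                      role = c("product", "product", "substrate"))
  model <- load_annotations(genes, links, lib)
  pred <- context_candidates(neighbors(model, "t", 2000L), model, lib,
                             reference = "target_sub")
  expect_equal(pred$candidates$compound_id[1], "planted")
  expect_gt(pred$candidates$ti[1], 0.6)
  expect_lt(max(pred$candidates$ti[-1]), 0.3)
})

test_that("recovery counts only informative targets", {
  lib <- toy_library()
  mk_pred <- function(cpd) {
    structure(list(status = "ok",
                   candidates = data.frame(compound_id = cpd,
                                           source_gene = "g", role = "product",
                                           gap_bp = 0L, adjacent = TRUE,
                                           ti = NA_real_)),
              class = "context_prediction")
  }
  none <- structure(list(status = "no-information",
                         candidates = data.frame(compound_id = character(0))),
                    class = "context_prediction")
  preds <- list(t1 = mk_pred("cpdA"), t2 = mk_pred("cpdA"),
                t3 = mk_pred("cpdA"), t4 = mk_pred("cpdA"),
                t5 = mk_pred("cpdC"), t6 = none)
  truth <- c(t1 = "cpdA", t2 = "cpdA", t3 = "cpdA", t4 = "cpdA",
             t5 = "cpdA", t6 = "cpdA")
  rec <- context_recovery(preds, truth, lib, ti_success = 0.85)
  expect_equal(rec$n_informative, 5)
  expect_equal(rec$recovery, 0.8)  # 4 of 5 informative targets

  all_none <- list(t1 = none)
  rec0 <- context_recovery(all_none, truth[1], lib)
  expect_true(is.na(rec0$recovery))
})
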