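test_that("cophenetic_matrix equals hand path sums and the tracing oracle", {
  t2 <- ape::read.tree(text = "(A:0.1,B:0.2);")
  expect_equal(cophenetic_matrix(t2)["A", "B"], 0.3)

  t3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  d3 <- cophenetic_matrix(t3)
  expect_equal(d3["A", "B"], 2)
  expect_equal(d3["A", "C"], 4)
  expect_equal(d3["B", "C"], 4)

  set.seed(1)
  for (n in c(5, 12, 32)) {
    tr <- ape::rtree(n)
    d <- cophenetic_matrix(tr)
    expect_equal(d, oracle_tree_distances(tr)[rownames(d), colnames(d)],
                 tolerance = 1e-10)
  }

  bad <- ape::rtree(4)
  bad$edge.length <- NULL
  expect_error(cophenetic_matrix(bad), "branch lengths")
})

test_that("the one-percent rule returns the exhaustive-scan optimum", {
  # four equidistant leaves: every cut up to k = 4 keeps all groups major
  d4 <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d4) <- 0
  g4 <- cut_by_one_percent_rule(d4, kmax = 4)
  expect_equal(g4$k, 4)
  expect_equal(g4$n_major, 4)

  # zero distances: every cut of k tied leaves yields k one-member groups,
  # all major at this size, so the scan maximum sits at kmax — and the
  # returned k must be the smallest k attaining the scan maximum
  d0 <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  g0 <- cut_by_one_percent_rule(d0, kmax = 5)
  scan0 <- oracle_major_group_scan(d0, 5)
  expect_equal(g0$n_major, max(scan0))
  expect_equal(g0$k, (2:5)[which.max(scan0)])

  # three tight clades (40/40/20) plus two far outliers among ~100 leaves:
  # high k isolates sub-1% outlier singletons
  set.seed(5)
  centers <- c(0, 10, 20)
  pts <- c(rnorm(40, centers[1], 0.1), rnorm(40, centers[2], 0.1),
           rnorm(20, centers[3], 0.1), 100, 200)
  names(pts) <- sprintf("L%03d", seq_along(pts))
  dd <- as.matrix(dist(pts))
  gr <- cut_by_one_percent_rule(dd, kmax = 20)
  scan <- oracle_major_group_scan(dd, 20)
  expect_equal(gr$n_major, max(scan))
  expect_equal(gr$k, (2:20)[which.max(scan)])  # smallest k among the argmax

  # fractions always sum to one and n_major <= k
  expect_equal(sum(gr$fractions), 1)
  expect_lte(gr$n_major, gr$k)

  for (seed in 1:5) {
    tr <- ape::rtree(30)
    d <- cophenetic_matrix(tr)
    g <- cut_by_one_percent_rule(d, kmax = 10)
    scan <- oracle_major_group_scan(d, 10)
    expect_equal(g$n_major, max(scan), info = paste("seed", seed))
  }
})

test_that("assign_group is exact for references and order-invariant", {
  refs <- c(r1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
            r2 = "MKTAYIAKQRQISFVKSHFSRQAEERLGAIEVQ",
            r3 = "WWPLNNGGHHEEDDKKRRSSTTVVYYFFMMIIL",
            r4 = "WWPLNNGGHHEEDDKKRRSSTTVVYYAFMMIIL")
  labels <- c(r1 = "A", r2 = "A", r3 = "B", r4 = "B")
  hit <- assign_group(refs[["r1"]], refs, labels)
  expect_equal(hit$group, "A")
  expect_gt(hit$margin, 0)

  # a sequence rebuilt from a reference's shuffled 3-mers keeps its profile
  kmers <- substring(refs[["r3"]], seq(1, nchar(refs[["r3"]]) - 2, by = 3),
                     seq(3, nchar(refs[["r3"]]), by = 3))
  set.seed(4)
  shuffled <- paste(sample(kmers), collapse = "")
  expect_equal(assign_group(shuffled, refs, labels)$group, "B")

  expect_error(assign_group("MKT", character(0), character(0)), "reference")
  expect_error(assign_group("MK", refs, labels), "k-mer")
})

test_that("clade labels are recovered from synthetic sequences", {
  w <- gen_tree_and_seqs(world_config(seed = 17))
  labels <- w$labels
  acc <- vapply(seq_along(w$sequences), function(i) {
    hit <- assign_group(w$sequences[[i]], w$sequences[-i], labels[-i])
    hit$group == labels[[i]]
  }, logical(1))
  expect_gte(mean(acc), 0.95)
})

test_that("scan_motifs finds the P450 signatures with variant flags", {
  hits <- scan_motifs("FGAGAHACVG")
  heme <- hits[hits$motif == "heme_binding", ]
  expect_equal(nrow(heme), 1L)
  expect_equal(heme$start, 1L)
  expect_equal(heme$variant, "H")

  expect_equal(scan_motifs("EAAR")$motif, "EXXR")

  pr <- scan_motifs("AGTDTT")
  expect_equal(pr$motif, "proton_relay")
  expect_equal(pr$variant, "D")

  nr <- scan_motifs("XXNRDPXX")
  expect_equal(nr[nr$motif == "NRDP", "variant"], "N")

  # group-N style heme motif with terminal A instead of G
  relaxed <- scan_motifs("FSAGARACVA")
  expect_equal(relaxed[relaxed$motif == "heme_binding", "start"], 1L)

  expect_equal(nrow(scan_motifs("PPPPPPP")), 0L)

  # every reported hit re-validates against its own pattern
  set.seed(9)
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  pats <- c(heme_binding = "^F[GS].G.[HR].C.[GA]$", EXXR = "^E..R$",
            proton_relay = "^[AG]G.[DE]T[TS]$", NRDP = "^[NH]RDP$")
  for (i in 1:20) {
    s <- paste(sample(aa, 120, replace = TRUE), collapse = "")
    h <- scan_motifs(s)
    if (nrow(h) > 0) {
      expect_true(all(mapply(grepl, pats[h$motif], h$match)))
      expect_true(all(substring(s, h$start, h$end) == h$match))
    }
  }
})

test_that("diagnostic residue checks follow the group profiles", {
  # build a sequence carrying exactly the group-L diagnostics
  chars <- rep("A", 400)
  profile <- baccyp_diagnostic_profile()
  for (p in names(profile$L)) chars[as.integer(p)] <- profile$L[[p]]
  seq <- paste(chars, collapse = "")
  res <- check_diagnostics(seq)
  expect_equal(res$fraction[res$group == "L"], 1.0)
  # K's diagnostics are a subset of L's
  expect_equal(res$fraction[res$group == "K"], 1.0)

  # groups without diagnostics are flagged, not scored
  expect_true(res$no_diagnostics[res$group == "A"])
  expect_true(is.na(res$fraction[res$group == "A"]))

  # a W at 155 fully satisfies group H (its only diagnostic) and one of
  # group I's four
  chars2 <- rep("A", 400)
  chars2[155] <- "W"
  chars2[128] <- "Q"  # break the alanine default at I's position 128
  res2 <- check_diagnostics(paste(chars2, collapse = ""))
  expect_equal(res2$fraction[res2$group == "H"], 1.0)
  expect_equal(res2$fraction[res2$group == "I"], 1 / 4)

  # positions beyond the mapped range are reported as unmatchable
  short <- check_diagnostics(paste(rep("A", 100), collapse = ""))
  expect_gt(short$n_out_of_range[short$group == "B"], 0)
})

test_that("pairwise identity comes from global alignment without end gaps", {
  expect_equal(pairwise_identity("MKTAYIAK", "MKTAYIAK"), 100)
  expect_equal(pairwise_identity("AAAA", "AATA"), 75)
  a <- "MKTAYIAKQRQISFVKSHF"
  b <- "MKTAYLAKQRQISFVKAHF"
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  expect_error(pairwise_identity("", "AA"), "empty")
  # a terminal extension does not dilute identity
  expect_equal(pairwise_identity("MKTAYIAK", "MKTAYIAKWWWW"), 100)
})

test_that("identity strata split substrate similarities correctly", {
  one <- data.frame(identity = 80, ti = 0.9)
  s <- identity_vs_substrate_ti(one)
  expect_equal(s$high_identity, 0.9)

  # "over 70%" is strict: a pair at exactly 70 stays out
  boundary <- data.frame(identity = c(70, 71), ti = c(0.5, 0.6))
  sb <- identity_vs_substrate_ti(boundary)
  expect_equal(sb$high_identity, 0.6)

  # correlated identity/TI: the high-identity stratum is enriched
  set.seed(21)
  ident <- runif(300, 0, 100)
  ti <- pmin(1, pmax(0, ident / 100 * 0.8 + rnorm(300, 0, 0.1)))
  sc <- identity_vs_substrate_ti(data.frame(identity = ident, ti = ti))
  expect_gt(mean(sc$high_identity), mean(sc$all))

  expect_warning(identity_vs_substrate_ti(data.frame(identity = 10, ti = 0.2)),
                 "empty")
})
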