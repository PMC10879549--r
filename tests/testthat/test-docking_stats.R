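test_that("grid configuration follows the ligand-size rule", {
  g30 <- make_grid_config(30, c(0, 0, 0), c(0, 0, 1))
  expect_equal(g30$edge, 40)
  expect_equal(g30$spacing, 0.375)
  expect_equal(g30$center, c(0, 0, 10))

  # the 62-atom long-chain fatty acid case needs the large grid
  expect_equal(make_grid_config(62, c(1, 2, 3), c(1, 0, 0))$edge, 60)
  # the unaddressed boundary count gets the permissive grid
  expect_equal(make_grid_config(35, c(0, 0, 0), c(0, 1, 0))$edge, 60)
  expect_equal(make_grid_config(34, c(0, 0, 0), c(0, 1, 0))$edge, 40)

  off_center <- make_grid_config(10, c(5, -2, 1), c(0, 0, -1))
  expect_equal(off_center$center, c(5, -2, -9))

  expect_error(make_grid_config(10, c(0, 0, 0), c(0, 0, 2)), "unit")

  gpf <- format_gpf(g30)
  expect_match(gpf[1], "npts 107 107 107")
  expect_match(gpf[2], "0.375")
})

test_that("heme normal helper fits the nitrogen plane", {
  # four nitrogens in the z = 2 plane
  nitro <- rbind(c(1, 0, 2), c(0, 1, 2), c(-1, 0, 2), c(0, -1, 2))
  n <- heme_normal_from_nitrogens(nitro)
  expect_equal(abs(n), c(0, 0, 1), tolerance = 1e-10)
  n_up <- heme_normal_from_nitrogens(nitro, toward = c(0, 0, 50))
  expect_equal(n_up, c(0, 0, 1), tolerance = 1e-10)
})

test_that("bias specifications enforce the heme + three limit", {
  ok <- list(heme = list(atom = "FE-coord", reward = -2),
             additional = list(list(atom = "O1", reward = -1),
                               list(atom = "N2", reward = -1),
                               list(atom = "C3", reward = -0.5)))
  expect_silent(validate_bias_spec(ok))

  four <- ok
  four$additional <- c(four$additional, list(list(atom = "X", reward = -1)))
  expect_error(validate_bias_spec(four), "at most 3")

  expect_error(validate_bias_spec(list(additional = list())), "heme")
  pos <- list(heme = list(atom = "FE", reward = 1))
  expect_error(validate_bias_spec(pos), "<= 0")
})

test_that("the affinity filter is strict at pchembl 6", {
  rec <- data.frame(ligand = letters[1:5],
                    pchembl = c(5.5, 6.0, 6.1, 7.2, NA))
  f <- affinity_filter(rec)
  expect_setequal(f$kept$pchembl, c(6.1, 7.2))
  expect_equal(f$n_dropped_missing, 1)
  expect_equal(f$n_dropped_weak, 2)

  all_na <- data.frame(pchembl = c(NA_real_, NA_real_))
  fa <- affinity_filter(all_na)
  expect_equal(nrow(fa$kept), 0)
  expect_equal(fa$n_dropped_missing, 2)
})

test_that("Z-scores are standardised per receptor and affine-invariant", {
  rec <- data.frame(receptor = "r", ligand = c("a", "b", "c"),
                    energy_kcal = c(-10, -8, -6),
                    population = c(50, 20, 10), runs = 100)
  z <- zscore_table(rec)
  expect_equal(z$z_energy, c(-1, 0, 1))
  expect_equal(mean(z$z_population), 0, tolerance = 1e-12)
  expect_equal(sd(z$z_population), 1, tolerance = 1e-12)

  # affine rescaling of energies leaves the Z-scores unchanged
  rec2 <- rec
  rec2$energy_kcal <- 3.7 * rec$energy_kcal + 11
  expect_equal(zscore_table(rec2)$z_energy, z$z_energy, tolerance = 1e-12)

  flat <- rec
  flat$population <- c(30, 30, 30)
  zf <- zscore_table(flat)
  expect_equal(zf$z_population, c(0, 0, 0))
  expect_equal(attr(zf, "degenerate_axes"), "r")

  expect_error(zscore_table(rec[1, ]), "single ligand")
  bad <- rec; bad$population[1] <- 200
  expect_error(zscore_table(bad), "population")
})

test_that("binder calls respect the 0.9-of-true-positive boundary", {
  # panel engineered to put the TP at z ~ (-2, +2) and probes at the
  # spec'd boundary points
  mk <- function(ze, zp) {
    data.frame(receptor = "r", ligand = c("tp", "cand", sprintf("f%d", 1:6)),
               group = "g",
               z_energy = c(-2, ze, rep(NA, 6)), z_population = c(2, zp, rep(NA, 6)))
  }
  ztab <- data.frame(receptor = "r",
                     ligand = c("tp", "cand_in", "cand_out"),
                     group = c("gA", "gB", "gC"),
                     z_energy = c(-2, -1.9, -1.7),
                     z_population = c(2, 1.9, 1.9))
  for (mode in c("per_axis", "product", "norm")) {
    calls <- call_binders(ztab, c(r = "tp"), alpha = 0.9, mode = mode)
    expect_true(calls$is_binder[calls$ligand == "tp"], info = mode)
    expect_true(calls$is_binder[calls$ligand == "cand_in"], info = mode)
    if (mode != "norm") {
      # (-1.7, 1.9) falls short of 0.9 of the TP's joint extremity
      expect_false(calls$is_binder[calls$ligand == "cand_out"], info = mode)
    }
  }

  # degenerate panel: TP outside the favourable quadrant still a binder
  zdeg <- data.frame(receptor = "r", ligand = c("tp", "o"), group = "g",
                     z_energy = c(1, -1), z_population = c(-1, 1))
  expect_warning(cd <- call_binders(zdeg, c(r = "tp")), "degenerate")
  expect_true(cd$is_binder[cd$ligand == "tp"])

  expect_error(call_binders(ztab, c(r = "ghost")), "absent")
})

test_that("planted binders are recovered on the synthetic dock table", {
  cfg <- world_config(seed = 23)
  lib <- gen_compounds(cfg)
  groups <- sort(unique(lib$groups))
  receptors <- sprintf("RLP_%s", groups)
  panel <- data.frame(ligand = lib$ids, group = unname(lib$groups))
  bm <- setNames(lapply(groups, function(g) lib$ids[lib$groups == g][1:2]),
                 receptors)
  tab <- gen_dock_table(cfg, receptors, panel, bm)
  calls <- call_binders(zscore_table(tab), vapply(bm, `[`, "", 1), alpha = 0.9)
  key <- function(d) paste(d$receptor, d$ligand)
  truth <- tab$is_true_binder[match(key(calls), key(tab))]
  recall <- sum(calls$is_binder & truth) / sum(truth)
  fpr <- sum(calls$is_binder & !truth) / sum(!truth)
  expect_gte(recall, 0.9)
  expect_lte(fpr, 0.1)
})

test_that("selectivity matrix counts binders by group", {
  calls <- data.frame(
    receptor = rep(c("r1", "r2"), each = 4),
    ligand = sprintf("l%d", 1:8),
    group = rep(c("gA", "gA", "gB", "gB"), 2),
    is_binder = c(TRUE, TRUE, FALSE, FALSE,  TRUE, FALSE, TRUE, TRUE))
  sm <- selectivity_matrix(calls, c(r1 = "gA", r2 = "gB"))
  expect_equal(sm$matrix["r1", "gA"], 2L)
  expect_equal(sm$promiscuity[["r1"]], 1L)
  expect_true(sm$selective[["r1"]])
  expect_equal(sm$promiscuity[["r2"]], 2L)
  expect_false(sm$selective[["r2"]])
  # row sums equal total binder counts per receptor
  expect_equal(unname(rowSums(sm$matrix)), c(2, 3))

  none <- calls
  none$is_binder <- FALSE
  sm0 <- selectivity_matrix(none, c(r1 = "gA", r2 = "gB"))
  expect_true(all(sm0$matrix == 0))

  # a receptor planted to bind six groups shows promiscuity six
  many <- data.frame(receptor = "rx", ligand = sprintf("l%d", 1:12),
                     group = rep(sprintf("g%d", 1:6), 2),
                     is_binder = rep(c(TRUE, FALSE), each = 6))
  smx <- selectivity_matrix(many, c(rx = "g1"))
  expect_equal(smx$promiscuity[["rx"]], 6L)
})

test_that("task enumeration reproduces the panel arithmetic", {
  # 17 ligand groups, two ligands each plus one extra, give a 35-ligand
  # panel; against 15 receptors that is 525 docking calculations
  groups <- sprintf("grp%02d", 1:17)
  panel <- unlist(lapply(groups, function(g) paste0(g, "_", 1:2)))
  panel <- c(panel, "grp05_3")
  expect_length(panel, 35)
  receptors <- sprintf("RLP%02d", 1:15)
  tasks <- enumerate_tasks(receptors, panel)
  expect_equal(nrow(tasks), 525)

  expect_equal(nrow(enumerate_tasks("r", "l")), 1)
  expect_error(enumerate_tasks(c("r", "r"), "l"), "duplicate")
  expect_error(enumerate_tasks(character(0), "l"), "empty")
})
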