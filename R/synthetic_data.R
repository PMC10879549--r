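#' Configuration for a synthetic benchmark world
#'
#' Gathers every knob of the generators: a planted compound library with
#' high intra-group and low inter-group Tanimoto similarity, a
#' clade-structured tree with evolved sequences, operon-structured genomes
#' where a neighbour's product is the target P450's substrate, docking
#' tables where true binders are jointly extreme in energy and population,
#' and noisy model/reference structure pairs. Defaults mirror the regimes
#' the analyses assume: intra-group TI above 0.6 versus inter-group TI
#' below 0.35, 2000 bp context windows with planted producers at 1500 bp,
#' binder effect sizes of 3 kcal/mol in energy and 0.4 in population
#' fraction over 100 runs.
#'
#' @param seed Integer RNG seed; a fixed seed makes every generator
#'   byte-reproducible.
#' @param n_compound_groups,compounds_per_group,n_bits,scaffold_density,member_flips
#'   Compound library shape: groups, members, fingerprint length, expected
#'   scaffold bit density, bit flips per member.
#' @param intra_ti_range,inter_ti_ceiling Design targets the generated
#'   library must satisfy (checked post-generation).
#' @param n_clades,leaves_per_clade,seq_len,divergence,clade_divergence
#'   Tree/sequence shape: within-clade leaf divergence and clade-ancestor
#'   divergence as per-site substitution probabilities.
#' @param n_genomes,decoys_per_genome,planted_gap_bp,decoy_gap_range,gene_len,contig_pad
#'   Genome shape for the operon benchmark: the producer sits at
#'   `planted_gap_bp` from the target, decoys at gaps spanning
#'   `decoy_gap_range` (farther than the producer, still inside the
#'   classic 2000 bp window).
#' @param dock_mu0,dock_sigma_e,dock_p0,dock_delta_e,dock_delta_p,dock_runs
#'   Docking score model: non-binder energy mean/sd (kcal/mol), non-binder
#'   population fraction, binder offsets, runs per docking.
#' @return A `world_config` list.
#' @export
world_config <- function(seed = 1L,
                         n_compound_groups = 8L, compounds_per_group = 6L,
                         n_bits = 256L, scaffold_density = 0.3,
                         member_flips = 8L,
                         intra_ti_range = c(0.6, 1.0), inter_ti_ceiling = 0.35,
                         n_clades = 5L, leaves_per_clade = 12L,
                         seq_len = 300L, divergence = 0.1,
                         clade_divergence = 0.5,
                         n_genomes = 200L, decoys_per_genome = 4L,
                         planted_gap_bp = 1500L,
                         decoy_gap_range = c(1600L, 1950L),
                         gene_len = 900L, contig_pad = 5000L,
                         dock_mu0 = -6, dock_sigma_e = 0.3,
                         dock_p0 = 0.2, dock_delta_e = 3,
                         dock_delta_p = 0.4, dock_runs = 100L) {
  if (intra_ti_range[1L] <= inter_ti_ceiling) {
    stop("infeasible design: intra-TI range must sit above the inter-TI ceiling")
  }
  cfg <- as.list(environment())
  class(cfg) <- "world_config"
  cfg
}

#' Generate a compound library with planted group structure
#'
#' Each group gets a random scaffold fingerprint; members are the scaffold
#' with `member_flips` random bit flips, so same-group pairs stay highly
#' similar while cross-group pairs share only background bits. The
#' generated library is checked against the config's design targets
#' (mean intra-group TI within `intra_ti_range`, mean inter-group TI below
#' `inter_ti_ceiling`) and generation fails loudly if they are missed.
#'
#' @param config A [world_config()].
#' @return A `compound_library` with true group labels.
#' @export
gen_compounds <- function(config) {
  set.seed(config$seed + 101L)
  nb <- config$n_bits
  ids <- character(0); groups <- character(0)
  fps <- NULL
  for (g in seq_len(config$n_compound_groups)) {
    scaffold <- as.integer(stats::runif(nb) < config$scaffold_density)
    for (m in seq_len(config$compounds_per_group)) {
      fp <- scaffold
      if (config$member_flips > 0L) {
        flip <- sample.int(nb, config$member_flips)
        fp[flip] <- 1L - fp[flip]
      }
      if (sum(fp) == 0L) fp[sample.int(nb, 1L)] <- 1L
      ids <- c(ids, sprintf("cpd_g%02d_m%02d", g, m))
      groups <- c(groups, sprintf("G%02d", g))
      fps <- rbind(fps, fp)
    }
  }
  rownames(fps) <- ids
  lib <- compound_library(ids, fps, groups = groups)
  sim <- tanimoto_matrix(lib$fingerprints)
  dist <- intra_inter_distributions(sim, lib$groups)
  if (mean(dist$intra) < config$intra_ti_range[1L] ||
      mean(dist$intra) > config$intra_ti_range[2L] ||
      mean(dist$inter) > config$inter_ti_ceiling) {
    stop(sprintf(
      "generated library misses design targets (intra %.3f, inter %.3f)",
      mean(dist$intra), mean(dist$inter)))
  }
  lib
}

#' Generate a clade-structured tree with evolved sequences
#'
#' Builds a star-of-stars tree (clades on long stems, leaves on short
#' pendant branches) and evolves amino-acid sequences down it: a random
#' root sequence is mutated per clade at `clade_divergence`, then per leaf
#' at `divergence` (per-site substitution probabilities). Within-clade
#' cophenetic distances are therefore strictly smaller than between-clade
#' ones, and leaves carry their clade label.
#'
#' @param config A [world_config()].
#' @return List with `tree` (ape phylo), `sequences` (named character),
#'   `labels` (leaf -> clade letter).
#' @export
gen_tree_and_seqs <- function(config) {
  set.seed(config$seed + 202L)
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  mutate <- function(seq, p) {
    hit <- stats::runif(length(seq)) < p
    seq[hit] <- sample(aa, sum(hit), replace = TRUE)
    seq
  }
  root <- sample(aa, config$seq_len, replace = TRUE)
  clades <- group_letters(config$n_clades)
  seqs <- character(0); labels <- character(0)
  subtrees <- character(config$n_clades)
  for (ci in seq_len(config$n_clades)) {
    anc <- mutate(root, config$clade_divergence)
    tips <- character(config$leaves_per_clade)
    for (li in seq_len(config$leaves_per_clade)) {
      id <- sprintf("seq_%s%02d", clades[ci], li)
      leaf_seq <- mutate(anc, config$divergence)
      seqs[id] <- paste(leaf_seq, collapse = "")
      labels[id] <- clades[ci]
      tips[li] <- sprintf("%s:%.4f", id, 0.02 + stats::runif(1L, 0, 0.08))
    }
    subtrees[ci] <- sprintf("(%s):%.4f", paste(tips, collapse = ","),
                            0.5 + stats::runif(1L, 0, 0.3))
  }
  tree <- ape::read.tree(text = sprintf("(%s);", paste(subtrees, collapse = ",")))
  list(tree = tree, sequences = seqs, labels = labels)
}

#' Generate operon-structured genome annotations
#'
#' One genome per target: the target BacCYP gene sits mid-contig with a
#' planted "producer" neighbour at `planted_gap_bp` whose annotated
#' product is the target's true substrate, plus decoy genes further away
#' linked to random compounds from other groups. The truth table maps each
#' target to its substrate.
#'
#' @param config A [world_config()].
#' @param library `compound_library` with group labels supplying substrates
#'   and decoy compounds.
#' @return List with `model` (a `genome_model`), `targets` (character),
#'   `truth` (named: target gene -> true compound id).
#' @export
gen_genomes <- function(config, library) {
  if (is.null(library$groups)) stop("library must carry group labels")
  set.seed(config$seed + 303L)
  genes <- NULL; links <- NULL
  targets <- character(config$n_genomes)
  truth <- character(config$n_genomes)
  glen <- config$gene_len
  for (gi in seq_len(config$n_genomes)) {
    contig <- sprintf("contig_%03d", gi)
    tid <- sprintf("bacCYP_%03d", gi)
    tstart <- config$contig_pad
    tend <- tstart + glen - 1L
    substrate <- sample(library$ids, 1L)
    targets[gi] <- tid
    truth[gi] <- substrate
    prod_end <- tstart - config$planted_gap_bp - 1L
    prod_start <- prod_end - glen + 1L
    pid <- sprintf("producer_%03d", gi)
    genes <- rbind(genes,
      data.frame(gene_id = tid, contig = contig, start = tstart, end = tend,
                 strand = "+", stringsAsFactors = FALSE),
      data.frame(gene_id = pid, contig = contig, start = prod_start,
                 end = prod_end, strand = "+", stringsAsFactors = FALSE))
    links <- rbind(links,
      data.frame(gene_id = pid, compound_id = substrate, role = "product",
                 stringsAsFactors = FALSE))
    if (config$decoys_per_genome > 0L) {
      other <- library$ids[library$groups[library$ids] != library$groups[[substrate]]]
      decoy_gaps <- as.integer(round(seq(config$decoy_gap_range[1L],
                                         config$decoy_gap_range[2L],
                                         length.out = max(config$decoys_per_genome, 2L))))
      for (di in seq_len(config$decoys_per_genome)) {
        did <- sprintf("decoy_%03d_%d", gi, di)
        # decoys sit downstream at gaps beyond the planted producer's
        # (farther, less plausible operon partners) yet inside the
        # classic 2000 bp search window
        dstart <- tend + decoy_gaps[di] + 1L
        genes <- rbind(genes,
          data.frame(gene_id = did, contig = contig, start = dstart,
                     end = dstart + glen - 1L,
                     strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE))
        links <- rbind(links,
          data.frame(gene_id = did, compound_id = sample(other, 1L),
                     role = sample(c("product", "substrate"), 1L),
                     stringsAsFactors = FALSE))
      }
    }
  }
  names(truth) <- targets
  model <- load_annotations(genes, links, library)
  list(model = model, targets = targets, truth = truth)
}

#' Generate a docking score table with planted binders
#'
#' Non-binders draw their best-pose energy from Normal(mu0, sigma_e) and
#' their best-cluster population from Binomial(runs, p0); each receptor's
#' true ligands get the energy offset `-dock_delta_e` and the population
#' offset `+dock_delta_p`, making them jointly extreme on both axes — the
#' upper-left-quadrant structure binder calling relies on.
#'
#' @param config A [world_config()].
#' @param receptors Character vector of receptor ids.
#' @param panel data.frame with columns `ligand`, `group`.
#' @param binder_map Named list receptor -> character vector of its true
#'   ligand ids.
#' @return data.frame with receptor, ligand, group, energy_kcal,
#'   population, runs, is_true_binder.
#' @export
gen_dock_table <- function(config, receptors, panel, binder_map) {
  set.seed(config$seed + 404L)
  stopifnot(all(names(binder_map) %in% receptors))
  rows <- lapply(receptors, function(rec) {
    true <- binder_map[[rec]] %||% character(0)
    is_b <- panel$ligand %in% true
    mu <- config$dock_mu0 - ifelse(is_b, config$dock_delta_e, 0)
    p <- pmin(1, config$dock_p0 + ifelse(is_b, config$dock_delta_p, 0))
    data.frame(receptor = rec, ligand = panel$ligand, group = panel$group,
               energy_kcal = stats::rnorm(nrow(panel), mu, config$dock_sigma_e),
               population = stats::rbinom(nrow(panel), config$dock_runs, p),
               runs = config$dock_runs, is_true_binder = is_b,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a model/reference structure pair with known noise
#'
#' The reference is a self-avoiding random CA walk with 3.8 Å steps; the
#' model is the reference under a random rigid motion plus isotropic
#' Gaussian coordinate noise of sd `sigma`, applied to the whole chain or
#' only to the listed active-site residues.
#'
#' @param config A [world_config()].
#' @param n_res Number of residues.
#' @param sigma Coordinate noise sd (Å).
#' @param active_site_only Optional residue ids: noise restricted to them.
#' @return List with `reference`, `model` (coordinate data.frames) and
#'   `sigma`.
#' @export
gen_structures <- function(config, n_res = 200L, sigma = 0.5,
                           active_site_only = NULL) {
  set.seed(config$seed + 505L)
  steps <- matrix(stats::rnorm(3L * (n_res - 1L)), ncol = 3L)
  steps <- 3.8 * steps / sqrt(rowSums(steps^2))
  xyz <- rbind(c(0, 0, 0), apply(steps, 2L, cumsum))
  reference <- data.frame(residue = seq_len(n_res), atom = "CA",
                          x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L])
  rot <- random_rotation()
  trans <- stats::rnorm(3L, sd = 20)
  moved <- xyz %*% t(rot) + matrix(trans, n_res, 3L, byrow = TRUE)
  noisy <- if (is.null(active_site_only)) rep(TRUE, n_res) else
    reference$residue %in% active_site_only
  noise <- matrix(stats::rnorm(3L * n_res, sd = sigma), ncol = 3L) * noisy
  model <- reference
  model[, c("x", "y", "z")] <- moved + noise
  list(reference = reference, model = model, sigma = sigma)
}

random_rotation <- function() {
  q <- stats::rnorm(4L); q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

#' Generate a complete synthetic world
#'
#' Runs every generator under one config: compound library, tree and
#' sequences, operon genomes, a docking table over one receptor per
#' compound group (its true ligands = its group's first two members), and
#' one structure pair.
#'
#' @param config A [world_config()].
#' @return List with `library`, `phylo` (tree/sequences/labels), `genomes`,
#'   `dock` (list: table, receptors, receptor_groups, binder_map, panel)
#'   and `structures`.
#' @export
gen_world <- function(config = world_config()) {
  library <- gen_compounds(config)
  phylo <- gen_tree_and_seqs(config)
  genomes <- gen_genomes(config, library)
  groups <- sort(unique(library$groups))
  receptors <- sprintf("RLP_%s", groups)
  receptor_groups <- stats::setNames(groups, receptors)
  panel <- data.frame(ligand = library$ids, group = unname(library$groups),
                      stringsAsFactors = FALSE)
  binder_map <- stats::setNames(lapply(groups, function(g) {
    library$ids[library$groups == g][1:2]
  }), receptors)
  dock <- list(
    table = gen_dock_table(config, receptors, panel, binder_map),
    receptors = receptors, receptor_groups = receptor_groups,
    panel = panel, binder_map = binder_map)
  clades <- sort(unique(phylo$labels))
  group_priors <- stats::setNames(lapply(seq_along(clades), function(ci) {
    groups[(((ci - 1L) * 2L + 0:2) %% length(groups)) + 1L]
  }), clades)
  list(library = library, phylo = phylo, genomes = genomes, dock = dock,
       group_priors = group_priors,
       structures = gen_structures(config), config = config)
}

#' Write a synthetic world to plain-text files
#'
#' Writes lib.tsv, tree.nwk, seqs.fasta, labels.tsv, genes.tsv, links.tsv,
#' scores.tsv and truth.tsv under `dir`.
#'
#' @param world Output of [gen_world()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_compound_library(world$library, p("lib.tsv"))
  ape::write.tree(world$phylo$tree, p("tree.nwk"))
  writeLines(paste0(">", names(world$phylo$sequences), "\n",
                    world$phylo$sequences), p("seqs.fasta"))
  utils::write.table(
    data.frame(id = names(world$phylo$labels), clade = world$phylo$labels),
    p("labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(world$genomes$model$genes, p("genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(world$genomes$model$links, p("links.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(world$dock$table, p("scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(target = names(world$genomes$truth),
               compound = world$genomes$truth),
    p("truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
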