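#' Docking grid configuration for a ligand
#'
#' Applies the sizing rule used for AutoGrid maps over P450 active sites: a
#' cubic 40 Å grid for ligands with fewer than 35 atoms, 60 Å otherwise
#' (the boundary count 35 gets the permissive 60 Å grid), spacing 0.375 Å,
#' and the grid centre placed 10 Å above the heme plane along the supplied
#' unit normal.
#'
#' @param n_atoms Ligand atom count (>= 1).
#' @param heme_center Numeric xyz of the heme iron/plane centre (Å).
#' @param heme_normal Unit vector pointing from the heme plane towards the
#'   distal pocket.
#' @return A `grid_config`: list with `edge` (Å), `spacing` (Å), `center`.
#' @export
make_grid_config <- function(n_atoms, heme_center, heme_normal) {
  stopifnot(n_atoms >= 1, length(heme_center) == 3L, length(heme_normal) == 3L)
  if (abs(sqrt(sum(heme_normal^2)) - 1) > 1e-6) {
    stop("heme_normal must be a unit vector")
  }
  out <- list(edge = if (n_atoms < 35) 40 else 60,
              spacing = 0.375,
              center = as.numeric(heme_center) + 10 * as.numeric(heme_normal))
  class(out) <- "grid_config"
  out
}

#' @export
print.grid_config <- function(x, ...) {
  cat(sprintf("Grid: %g x %g x %g A, spacing %g A, center (%.3f, %.3f, %.3f)\n",
              x$edge, x$edge, x$edge, x$spacing,
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' AutoGrid-style parameter text for a grid configuration
#'
#' @param grid A `grid_config`.
#' @return Character vector of GPF-style lines (npts derived from edge and
#'   spacing, gridcenter, spacing).
#' @export
format_gpf <- function(grid) {
  stopifnot(inherits(grid, "grid_config"))
  npts <- round(grid$edge / grid$spacing)
  c(sprintf("npts %d %d %d", npts, npts, npts),
    sprintf("spacing %.3f", grid$spacing),
    sprintf("gridcenter %.3f %.3f %.3f",
            grid$center[1], grid$center[2], grid$center[3]))
}

#' Docking engine parameters used throughout
#'
#' @return Named list: `ga_run = 100` independent runs, `rmstol = 2.5` Å pose
#'   clustering tolerance.
#' @export
autodock_params <- function() {
  list(ga_run = 100L, rmstol = 2.5)
}

#' Least-squares heme plane normal from porphyrin nitrogen coordinates
#'
#' Fits a plane through the four pyrrole nitrogens by SVD and returns its
#' unit normal. The sign is chosen to point towards `toward` when given
#' (e.g. an axial-pocket atom), otherwise the normal with positive last
#' non-zero component is returned.
#'
#' @param nitrogens 4x3 matrix of xyz coordinates (Å).
#' @param toward Optional xyz; the normal is flipped to point at it.
#' @return Unit 3-vector.
#' @export
heme_normal_from_nitrogens <- function(nitrogens, toward = NULL) {
  m <- as.matrix(nitrogens)
  stopifnot(nrow(m) >= 3L, ncol(m) == 3L)
  centered <- sweep(m, 2L, colMeans(m))
  sv <- svd(centered)
  normal <- sv$v[, 3L]
  normal <- normal / sqrt(sum(normal^2))
  if (!is.null(toward)) {
    if (sum(normal * (as.numeric(toward) - colMeans(m))) < 0) normal <- -normal
  } else {
    nz <- which(abs(normal) > 1e-12)
    if (length(nz) && normal[max(nz)] < 0) normal <- -normal
  }
  normal
}

#' Validate a biased-docking specification
#'
#' A valid bias set has exactly one heme-coordination bias plus at most
#' three additional interaction biases; every bias is an energy reward, so
#' its value must be <= 0 kcal/mol.
#'
#' @param spec List with elements `heme` (list(atom, reward)) and
#'   `additional` (list of such lists, possibly empty).
#' @return The validated spec (invisibly classed `bias_spec`).
#' @export
validate_bias_spec <- function(spec) {
  if (is.null(spec$heme) || is.null(spec$heme$atom)) {
    stop("bias spec rejected: the heme-coordination bias is mandatory")
  }
  extra <- spec$additional %||% list()
  if (length(extra) > 3L) {
    stop("bias spec rejected: at most 3 additional biases are allowed (got ",
         length(extra), ")")
  }
  rewards <- c(spec$heme$reward, vapply(extra, function(b) b$reward %||% 0, numeric(1)))
  if (any(rewards > 0)) stop("bias rewards must be <= 0 (energy rewards)")
  class(spec) <- "bias_spec"
  invisible(spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter binding-assay records by pchembl affinity
#'
#' Keeps rows with pchembl strictly greater than 6 (i.e. affinity better
#' than 1 micromolar); rows with missing pchembl are dropped and counted.
#'
#' @param records data.frame with a numeric `pchembl` column.
#' @param threshold Strict lower bound (default 6).
#' @return List with `kept` (data.frame), `n_dropped_missing`,
#'   `n_dropped_weak`.
#' @export
affinity_filter <- function(records, threshold = 6) {
  stopifnot("pchembl" %in% names(records))
  missing <- is.na(records$pchembl)
  keep <- !missing & records$pchembl > threshold
  list(kept = records[keep, , drop = FALSE],
       n_dropped_missing = sum(missing),
       n_dropped_weak = sum(!missing & !keep))
}

#' Per-receptor Z-scores of docking energy and pose population
#'
#' Within one receptor's ligand panel, standardises the best-pose binding
#' energy and the best-cluster population fraction (population / runs) to
#' Z-scores using the sample standard deviation. A panel with zero spread
#' on an axis gets all-zero Z on that axis and a flag.
#'
#' @param records data.frame with columns receptor, ligand, energy_kcal,
#'   population, runs, and optionally group.
#' @return data.frame of the input plus pop_frac, z_energy, z_population,
#'   with attribute `degenerate_axes` naming receptors with a zero-spread
#'   axis.
#' @export
zscore_table <- function(records) {
  req <- c("receptor", "ligand", "energy_kcal", "population", "runs")
  stopifnot(all(req %in% names(records)))
  if (any(records$population < 0 | records$population > records$runs)) {
    stop("population must lie in [0, runs]")
  }
  if (any(!is.finite(records$energy_kcal))) stop("energies must be finite")
  records$pop_frac <- records$population / records$runs
  degenerate <- character(0)
  out <- lapply(split(records, records$receptor), function(df) {
    if (nrow(df) < 2L) {
      stop("receptor ", df$receptor[1L], " has a single ligand: no scale for Z-scores")
    }
    zs <- function(x) {
      s <- stats::sd(x)
      if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
    }
    if (stats::sd(df$energy_kcal) == 0 || stats::sd(df$pop_frac) == 0) {
      degenerate <<- c(degenerate, df$receptor[1L])
    }
    df$z_energy <- zs(df$energy_kcal)
    df$z_population <- zs(df$pop_frac)
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "degenerate_axes") <- unique(degenerate)
  res
}

#' Call binders from Z-scored docking results
#'
#' The true-positive ligand of a receptor sits in the upper-left quadrant
#' of the (Z-energy, Z-population) plane: strongly negative energy Z, high
#' population Z. A panel ligand is called a binder when it lies in that
#' quadrant and reaches `alpha` (default 0.9) of the true positive's joint
#' extremity. Three composites of the two Z-scores are available: the
#' default `"product"` compares `|z_energy * z_population|` against
#' `alpha^2` times the true positive's product (robust to noise splitting
#' unevenly across the axes); `"per_axis"` requires
#' `z_energy <= alpha * z_TP_energy` and
#' `z_population >= alpha * z_TP_population` separately; `"norm"` compares
#' Euclidean norms of the Z pairs.
#'
#' @param ztab Output of [zscore_table()] for one or more receptors.
#' @param true_positive Named character vector receptor -> its true-positive
#'   ligand id (or a single ligand id applied to every receptor).
#' @param alpha Fraction of the true-positive Z-scores required (0.9).
#' @param mode "product" (default), "per_axis" or "norm".
#' @return data.frame with receptor, ligand, group (when present),
#'   z_energy, z_population, margin_energy, margin_population, is_binder;
#'   attribute `degenerate_panels` lists receptors whose true positive is
#'   not in the favourable quadrant.
#' @export
call_binders <- function(ztab, true_positive, alpha = 0.9,
                         mode = c("product", "per_axis", "norm")) {
  mode <- match.arg(mode)
  degenerate <- character(0)
  out <- lapply(split(ztab, ztab$receptor), function(df) {
    rec <- df$receptor[1L]
    tp <- if (!is.null(names(true_positive))) true_positive[[rec]] else true_positive[[1L]]
    ti <- match(tp, df$ligand)
    if (is.na(ti)) stop("true positive ", tp, " absent from panel of ", rec)
    ze_tp <- df$z_energy[ti]; zp_tp <- df$z_population[ti]
    if (ze_tp >= 0 || zp_tp <= 0) {
      degenerate <<- c(degenerate, rec)
      warning("degenerate panel for ", rec,
              ": true positive not in the upper-left quadrant")
    }
    df$margin_energy <- ifelse(ze_tp != 0, df$z_energy / ze_tp, NA_real_)
    df$margin_population <- ifelse(zp_tp != 0, df$z_population / zp_tp, NA_real_)
    df$is_binder <- switch(mode,
      per_axis = df$z_energy <= alpha * ze_tp & df$z_population >= alpha * zp_tp,
      product = df$z_energy * df$z_population <= 0 &
        abs(df$z_energy * df$z_population) >= alpha^2 * abs(ze_tp * zp_tp) &
        df$z_energy <= 0 & df$z_population >= 0,
      norm = df$z_energy <= 0 & df$z_population >= 0 &
        sqrt(df$z_energy^2 + df$z_population^2) >=
          alpha * sqrt(ze_tp^2 + zp_tp^2))
    df$is_binder[ti] <- TRUE  # the true positive always qualifies
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  keep <- intersect(c("receptor", "ligand", "group", "z_energy", "z_population",
                      "margin_energy", "margin_population", "is_binder"), names(res))
  res <- res[, keep]
  attr(res, "degenerate_panels") <- unique(degenerate)
  res
}

#' Selectivity matrix and promiscuity of receptors over ligand groups
#'
#' Cross-tabulates binder calls: each cell counts the ligands of one group
#' called binders of one receptor. Promiscuity of a receptor is the number
#' of distinct ligand groups with at least one binder; a receptor is
#' "selective" when its binders all come from its own ligand group.
#'
#' @param calls Output of [call_binders()] with a `group` column.
#' @param receptor_groups Named vector receptor -> its own ligand group.
#' @return List with `matrix` (receptors x groups, counts), `promiscuity`
#'   (named integer), `selective` (named logical).
#' @export
selectivity_matrix <- function(calls, receptor_groups) {
  stopifnot("group" %in% names(calls))
  receptors <- sort(unique(calls$receptor))
  groups <- sort(unique(calls$group))
  if (length(groups) < 2L) stop("panel must cover at least 2 ligand groups")
  m <- matrix(0L, length(receptors), length(groups),
              dimnames = list(receptors, groups))
  b <- calls[calls$is_binder, , drop = FALSE]
  if (nrow(b) > 0L) {
    tab <- table(b$receptor, b$group)
    m[rownames(tab), colnames(tab)] <- tab
  }
  promiscuity <- apply(m, 1L, function(r) sum(r > 0L))
  selective <- vapply(receptors, function(r) {
    own <- receptor_groups[[r]]
    sum(m[r, ]) > 0L && all(m[r, colnames(m) != own] == 0L)
  }, logical(1))
  list(matrix = m, promiscuity = promiscuity,
       selective = stats::setNames(selective, receptors))
}

#' Enumerate the docking task list
#'
#' Full receptor x ligand cross product; with the classic panel of 15
#' representative receptors and 35 test ligands this yields 525 docking
#' calculations.
#'
#' @param receptors Character vector of receptor ids (unique).
#' @param ligands Character vector of ligand ids (unique).
#' @return data.frame with columns receptor, ligand; nrow = product of the
#'   two panel sizes.
#' @export
enumerate_tasks <- function(receptors, ligands) {
  if (length(receptors) == 0L || length(ligands) == 0L) stop("empty panel")
  if (anyDuplicated(receptors)) stop("duplicate receptor ids")
  if (anyDuplicated(ligands)) stop("duplicate ligand ids")
  tasks <- expand.grid(receptor = receptors, ligand = ligands,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tasks[order(tasks$receptor, tasks$ligand), ]
}

#' Read a docking score table
#'
#' @param path TSV with columns receptor, ligand, group, energy_kcal,
#'   population, runs.
#' @return data.frame.
#' @export
read_dock_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("receptor", "ligand", "energy_kcal", "population", "runs")
  if (!all(req %in% names(df))) {
    stop("dock table needs columns: ", paste(req, collapse = ", "))
  }
  df
}
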