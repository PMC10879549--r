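#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares superposition of two corresponding point sets by SVD of
#' the covariance matrix, constrained to a proper rotation (det = +1, never
#' a reflection). The returned RMSD is the minimum over all rigid motions.
#'
#' @param mobile,reference n x 3 coordinate matrices (Å), rows in
#'   correspondence, n >= 3 and not collinear.
#' @return List with `rotation` (3x3, det +1), `translation` (3-vector such
#'   that `transformed = mobile %*% t(rotation) + translation`), `rmsd`, and
#'   `transformed` coordinates.
#' @export
superpose <- function(mobile, reference) {
  m <- as.matrix(mobile); r <- as.matrix(reference)
  if (!all(dim(m) == dim(r)) || ncol(m) != 3L) stop("need matching n x 3 coordinate sets")
  if (nrow(m) < 3L) stop("need at least 3 corresponding points")
  if (any(!is.finite(m)) || any(!is.finite(r))) stop("non-finite coordinates")
  cm <- colMeans(m); cr <- colMeans(r)
  m0 <- sweep(m, 2L, cm); r0 <- sweep(r, 2L, cr)
  if (sum(svd(r0)$d > 1e-9) < 2L || sum(svd(m0)$d > 1e-9) < 2L) {
    stop("degenerate (collinear) point set: superposition is not unique")
  }
  h <- t(m0) %*% r0
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cr - as.numeric(rot %*% cm)
  fitted <- m %*% t(rot) + matrix(trans, nrow(m), 3L, byrow = TRUE)
  list(rotation = rot, translation = trans,
       rmsd = sqrt(mean(rowSums((fitted - r)^2))),
       transformed = fitted)
}

#' RMSD report for a structural model against a reference
#'
#' Three standard metrics: whole-domain RMSD over all corresponding atoms
#' and CA-RMSD over alpha carbons, each after its own optimal
#' superposition; and active-site RMSD over the atoms of the listed
#' residues, measured after the whole-domain CA superposition (so it
#' reflects the placement error of the site within the fold, not a local
#' refit). Correspondence is resolved by (residue id, atom name).
#'
#' @param model,reference Coordinate sets: data.frames with columns
#'   `residue`, `atom`, `x`, `y`, `z` (see [read_coords()]).
#' @param active_site Optional vector of residue ids defining the active
#'   site (the list is a required input: P450 active-site definitions vary
#'   by family).
#' @return An `rmsd_report`: list with `domain_rmsd`, `ca_rmsd`,
#'   `active_site_rmsd` (NA with flag when no list given), and per-metric
#'   atom counts.
#' @export
rmsd_report <- function(model, reference, active_site = NULL) {
  key <- function(df) paste(df$residue, df$atom, sep = "|")
  common <- intersect(key(model), key(reference))
  if (length(common) < 3L) stop("cannot resolve residue/atom correspondence")
  mi <- match(common, key(model)); ri <- match(common, key(reference))
  mc <- as.matrix(model[mi, c("x", "y", "z")])
  rc <- as.matrix(reference[ri, c("x", "y", "z")])
  res_ids <- model$residue[mi]; atoms <- model$atom[mi]

  fit_all <- superpose(mc, rc)
  is_ca <- atoms == "CA"
  if (sum(is_ca) < 3L) stop("need at least 3 CA atoms")
  fit_ca <- superpose(mc[is_ca, , drop = FALSE], rc[is_ca, , drop = FALSE])

  as_rmsd <- NA_real_; n_as <- 0L; as_flag <- is.null(active_site)
  if (!is.null(active_site)) {
    sel <- res_ids %in% active_site
    n_as <- sum(sel)
    if (n_as == 0L) {
      as_flag <- TRUE
      warning("no active-site atoms found; metric omitted")
    } else {
      moved <- mc %*% t(fit_ca$rotation) +
        matrix(fit_ca$translation, nrow(mc), 3L, byrow = TRUE)
      as_rmsd <- sqrt(mean(rowSums((moved[sel, , drop = FALSE] -
                                      rc[sel, , drop = FALSE])^2)))
    }
  }
  out <- list(domain_rmsd = fit_all$rmsd, ca_rmsd = fit_ca$rmsd,
              active_site_rmsd = as_rmsd,
              n_atoms = c(domain = nrow(mc), ca = sum(is_ca), active_site = n_as),
              active_site_omitted = as_flag)
  class(out) <- "rmsd_report"
  out
}

#' @export
print.rmsd_report <- function(x, ...) {
  cat(sprintf("RMSD: domain %.3f A (%d atoms), CA %.3f A (%d atoms)",
              x$domain_rmsd, x$n_atoms[["domain"]],
              x$ca_rmsd, x$n_atoms[["ca"]]))
  if (!x$active_site_omitted) {
    cat(sprintf(", active site %.3f A (%d atoms)",
                x$active_site_rmsd, x$n_atoms[["active_site"]]))
  }
  cat("\n")
  invisible(x)
}

#' Template tier from phylogenetic distance
#'
#' Buckets a template's phylogenetic distance to the modelling target into
#' the three tiers used when assessing homology-model quality: short
#' `[0, 2]`, mid `(2, 4]`, long `> 4` (right-closed at the shared
#' integer boundaries).
#'
#' @param phylo_distance Non-negative tree-metric distance(s).
#' @return Character vector in {"short", "mid", "long"}.
#' @export
template_tier <- function(phylo_distance) {
  if (any(phylo_distance < 0)) stop("phylogenetic distance must be >= 0")
  ifelse(phylo_distance <= 2, "short", ifelse(phylo_distance <= 4, "mid", "long"))
}

#' Select the best structural model by an external quality score
#'
#' @param scores Named numeric vector (model id -> score), e.g. DOPE
#'   (lower better) or pLDDT (higher better).
#' @param direction "lower_better" or "higher_better".
#' @return The winning model id (ties: lexicographically first id).
#' @export
select_best_model <- function(scores, direction = c("lower_better", "higher_better")) {
  direction <- match.arg(direction)
  if (length(scores) == 0L) stop("no models to select from")
  if (any(!is.finite(scores))) stop("scores must be finite")
  s <- if (direction == "lower_better") scores else -scores
  ids <- names(s)[order(s, names(s))]
  ids[1L]
}

#' Read a coordinate set from PDB or xyz TSV
#'
#' PDB files are read with [bio3d::read.pdb()] (first model, altloc blank
#' or 'A', optional chain filter); TSV files need columns residue, atom,
#' x, y, z.
#'
#' @param path File path (`.pdb` or TSV).
#' @param chain Optional chain id for PDB input.
#' @return data.frame with columns residue, atom, x, y, z.
#' @export
read_coords <- function(path, chain = NULL) {
  if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    pdb <- bio3d::read.pdb(path, multi = FALSE)
    at <- pdb$atom
    at <- at[at$type == "ATOM" & at$alt %in% c("", "A", NA), , drop = FALSE]
    if (!is.null(chain)) at <- at[at$chain == chain, , drop = FALSE]
    data.frame(residue = at$resno, atom = at$elety,
               x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    req <- c("residue", "atom", "x", "y", "z")
    if (!all(req %in% names(df))) stop("coordinate TSV needs columns: ",
                                       paste(req, collapse = ", "))
    df[, req]
  }
}
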