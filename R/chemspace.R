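#' Tanimoto similarity between two binary fingerprints
#'
#' The Tanimoto Index (TI) of two bit sets is |A ∩ B| / |A ∪ B|. It is the
#' standard 2D similarity measure for molecular fingerprints and the quantity
#' every similarity-based step of this package (compound clustering, genetic
#' context ranking) is built on.
#'
#' @param a,b Binary fingerprints: numeric/integer/logical vectors of equal
#'   length, interpreted as bit sets (non-zero = set).
#' @return A similarity in `[0, 1]`. Two all-zero fingerprints yield 0 with a
#'   warning (an empty molecule is similar to nothing, but fragment inputs
#'   should not abort a batch).
#' @examples
#' tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1))  # 2 shared / 4 in union = 0.5
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b))
  }
  a <- as.logical(a)
  b <- as.logical(b)
  union_n <- sum(a | b)
  if (union_n == 0L) {
    warning("both fingerprints are empty (all-zero); Tanimoto defined as 0")
    return(0)
  }
  sum(a & b) / union_n
}

#' All-pairs Tanimoto similarity matrix
#'
#' @param fingerprints 0/1 matrix, one row per compound, with rownames as
#'   compound ids.
#' @return Symmetric matrix of TI values with unit diagonal and the compound
#'   ids as dimnames.
#' @export
tanimoto_matrix <- function(fingerprints) {
  fp <- as.matrix(fingerprints)
  if (is.null(rownames(fp))) stop("fingerprint matrix needs rownames (compound ids)")
  if (anyDuplicated(rownames(fp))) stop("duplicate compound ids in fingerprint matrix")
  storage.mode(fp) <- "double"
  fp <- (fp != 0) * 1
  inter <- fp %*% t(fp)
  n_bits <- rowSums(fp)
  un <- outer(n_bits, n_bits, "+") - inter
  ti <- ifelse(un == 0, 0, inter / un)
  diag(ti) <- 1
  ti
}

#' Compute a molecular fingerprint from a SMILES string
#'
#' Parses the SMILES with Open Babel (through ChemmineR/ChemmineOB) and
#' returns a path-based FP2 fingerprint of 1024 bits. Identical SMILES always
#' give identical fingerprints. A light syntactic check (balanced parentheses
#' and ring-closure digits) rejects malformed strings before they reach the
#' parser, which is permissive about some truncations.
#'
#' @param smiles A single SMILES string.
#' @return Named integer 0/1 vector of length 1024.
#' @export
compute_fingerprint <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) || !nzchar(smiles)) {
    stop("empty or invalid SMILES input")
  }
  bal <- 0L
  for (ch in strsplit(smiles, "")[[1]]) {
    if (ch == "(") bal <- bal + 1L
    if (ch == ")") bal <- bal - 1L
    if (bal < 0L) break
  }
  digits <- gsub("[^0-9]", "", gsub("%[0-9]{2}", "", smiles))
  ring_ok <- all(table(strsplit(digits, "")[[1]]) %% 2 == 0)
  if (bal != 0L || !ring_ok) {
    stop("cannot parse SMILES: '", smiles, "'")
  }
  for (pkg in c("ChemmineR", "ChemmineOB")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop("package '", pkg, "' is required for SMILES input")
    }
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) stop("cannot parse SMILES: '", smiles, "'")
  )
  ChemmineR::cid(sdf) <- "query"
  fp <- ChemmineR::fingerprintOB(sdf, "FP2")
  bits <- as.integer(methods::slot(fp, "fpma")[1L, ])
  if (sum(bits) == 0L) stop("cannot parse SMILES: '", smiles, "' (no atoms)")
  names(bits) <- NULL
  bits
}

#' Butina sphere-exclusion clustering
#'
#' Greedy sphere-exclusion over a similarity matrix: every compound's
#' neighbours are those with TI at or above the cutoff; the unassigned
#' compound with the most unassigned neighbours becomes the next cluster
#' centroid and absorbs those neighbours; compounds left without any
#' above-cutoff partner end as singletons. Ties on neighbour count are broken
#' by lexicographic id so the partition is deterministic.
#'
#' @param sim Symmetric similarity matrix with unit diagonal and dimnames.
#' @param cutoff Similarity threshold in (0, 1); a pair with TI >= cutoff is
#'   neighbour-linked. Distance-form thresholds (1 - TI) must be converted by
#'   the caller.
#' @return An object of class `butina_clustering`: list with `labels` (named
#'   integer vector, cluster index per compound, 0-based and contiguous),
#'   `centroids` (cluster index -> centroid id for non-singleton clusters),
#'   `singletons` (character vector of ids) and `cutoff`.
#' @export
butina_cluster <- function(sim, cutoff) {
  stopifnot(is.matrix(sim))
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0, 1)")
  ids <- rownames(sim)
  n <- length(ids)
  out <- list(labels = integer(0), centroids = character(0),
              singletons = character(0), cutoff = cutoff)
  class(out) <- "butina_clustering"
  if (n == 0L) return(out)
  if (!isTRUE(all.equal(sim, t(sim), tolerance = 1e-8))) {
    stop("similarity matrix is not symmetric")
  }
  nbr <- sim >= cutoff
  diag(nbr) <- FALSE
  assigned <- rep(FALSE, n)
  labels <- rep(NA_integer_, n)
  centroids <- character(0)
  k <- 0L
  repeat {
    free <- which(!assigned)
    if (length(free) == 0L) break
    counts <- vapply(free, function(i) sum(nbr[i, !assigned]), integer(1))
    best <- free[order(-counts, ids[free])][1L]
    members <- c(best, which(nbr[best, ] & !assigned))
    members <- unique(members)
    labels[members] <- k
    assigned[members] <- TRUE
    if (length(members) > 1L) {
      centroids[as.character(k)] <- ids[best]
    }
    k <- k + 1L
  }
  names(labels) <- ids
  singles <- ids[labels %in% as.integer(names(table(labels))[table(labels) == 1L])]
  out$labels <- labels
  out$centroids <- centroids
  out$singletons <- singles
  out
}

#' @export
print.butina_clustering <- function(x, ...) {
  sizes <- table(x$labels)
  cat("Butina clustering at cutoff", x$cutoff, "\n")
  cat("  ", length(x$labels), "compounds in", length(sizes), "clusters;",
      length(x$singletons), "singletons\n")
  invisible(x)
}

#' Choose a Butina cutoff balancing cluster count against singletons
#'
#' Scans candidate similarity cutoffs, clustering at each, and reports the
#' number of real (>= 2 member) clusters and the singleton fraction. The
#' chosen cutoff minimises the singleton fraction among candidates producing
#' at least `floor` real clusters; ties go to the larger cutoff (tighter
#' clusters). When no candidate reaches the floor the overall
#' singleton-minimiser is returned with `floor_met = FALSE`.
#'
#' @param sim Similarity matrix (see [butina_cluster()]).
#' @param candidates Numeric vector of cutoffs in (0, 1).
#' @param floor Minimum acceptable number of clusters with >= 2 members.
#' @return List with `cutoff` (chosen), `floor_met` (logical) and `scan`
#'   (data.frame: cutoff, n_clusters_ge2, singleton_fraction).
#' @export
choose_cutoff <- function(sim, candidates, floor = 2L) {
  if (length(candidates) < 1L) stop("need at least one candidate cutoff")
  n <- nrow(sim)
  scan <- do.call(rbind, lapply(candidates, function(ct) {
    cl <- butina_cluster(sim, ct)
    sizes <- table(cl$labels)
    data.frame(cutoff = ct,
               n_clusters_ge2 = sum(sizes >= 2L),
               singleton_fraction = length(cl$singletons) / n)
  }))
  ok <- scan$n_clusters_ge2 >= floor
  pool <- if (any(ok)) scan[ok, ] else scan
  pool <- pool[order(pool$singleton_fraction, -pool$cutoff), ]
  list(cutoff = pool$cutoff[1L], floor_met = any(ok), scan = scan)
}

#' Intra- and inter-group Tanimoto distributions
#'
#' Splits all unordered compound pairs into same-group (intra) and
#' cross-group (inter) pairs and returns the corresponding TI values, the
#' inputs for the classic paired-histogram view of how chemically coherent a
#' grouping is.
#'
#' @param sim Similarity matrix with compound ids as dimnames.
#' @param groups Named group labels covering the matrix ids.
#' @return List with numeric vectors `intra` and `inter`;
#'   `length(intra) + length(inter) == n(n-1)/2`.
#' @export
intra_inter_distributions <- function(sim, groups) {
  ids <- rownames(sim)
  if (!all(ids %in% names(groups))) stop("group labels missing for some compounds")
  g <- groups[ids]
  if (length(unique(g)) < 2L) {
    warning("only one group present: inter-group distribution is empty")
  }
  same <- outer(g, g, "==")
  ut <- upper.tri(sim)
  list(intra = sim[ut & same], inter = sim[ut & !same])
}

#' Read a compound library from TSV
#'
#' Expected columns: `id`, then any of `smiles`, `fingerprint` (hex string)
#' and `group`. Fingerprints are taken from the hex column when present,
#' otherwise computed from SMILES.
#'
#' @param path TSV file path.
#' @param n_bits Fingerprint length used to decode hex strings.
#' @return A `compound_library`: list with `ids`, `fingerprints` (0/1 matrix),
#'   `groups` (named vector, may contain NA) and optional `smiles`.
#' @export
read_compound_library <- function(path, n_bits = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("compound library needs an 'id' column")
  if (anyDuplicated(df$id)) stop("duplicate compound ids in library")
  if ("fingerprint" %in% names(df)) {
    fps <- t(vapply(df$fingerprint, hex_to_bits, integer(hex_n_bits(df$fingerprint[1L], n_bits)),
                    n_bits = n_bits))
  } else if ("smiles" %in% names(df)) {
    fps <- t(vapply(df$smiles, compute_fingerprint, integer(1024L)))
  } else {
    stop("library needs a 'fingerprint' or 'smiles' column")
  }
  rownames(fps) <- df$id
  compound_library(df$id, fps,
                   groups = if ("group" %in% names(df)) df$group else NULL,
                   smiles = if ("smiles" %in% names(df)) df$smiles else NULL)
}

#' Construct a compound library object
#'
#' @param ids Character vector of unique compound ids.
#' @param fingerprints 0/1 matrix, one row per id, equal lengths.
#' @param groups Optional group labels (recycled names from `ids`).
#' @param smiles Optional SMILES strings.
#' @return An object of class `compound_library`.
#' @export
compound_library <- function(ids, fingerprints, groups = NULL, smiles = NULL) {
  fps <- as.matrix(fingerprints)
  stopifnot(length(ids) == nrow(fps))
  if (anyDuplicated(ids)) stop("compound ids must be unique")
  if (any(rowSums(fps != 0) == 0L)) {
    warning("library contains all-zero fingerprints")
  }
  rownames(fps) <- ids
  obj <- list(ids = as.character(ids), fingerprints = fps,
              groups = if (is.null(groups)) NULL else stats::setNames(as.character(groups), ids),
              smiles = if (is.null(smiles)) NULL else stats::setNames(as.character(smiles), ids))
  class(obj) <- "compound_library"
  obj
}

#' @export
print.compound_library <- function(x, ...) {
  cat("Compound library:", length(x$ids), "compounds,",
      ncol(x$fingerprints), "fingerprint bits")
  if (!is.null(x$groups)) {
    cat(",", length(unique(stats::na.omit(x$groups))), "groups")
  }
  cat("\n")
  invisible(x)
}

#' Write a compound library to TSV (fingerprints as hex)
#'
#' @param library A `compound_library`.
#' @param path Output TSV path.
#' @export
write_compound_library <- function(library, path) {
  df <- data.frame(id = library$ids,
                   fingerprint = apply(library$fingerprints, 1L, bits_to_hex),
                   stringsAsFactors = FALSE)
  if (!is.null(library$groups)) df$group <- unname(library$groups)
  if (!is.null(library$smiles)) df$smiles <- unname(library$smiles)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

bits_to_hex <- function(bits) {
  bits <- as.integer(bits != 0)
  pad <- (4L - length(bits) %% 4L) %% 4L
  bits <- c(bits, rep(0L, pad))
  nyb <- matrix(bits, nrow = 4L)
  paste(sprintf("%x", colSums(nyb * c(8L, 4L, 2L, 1L))), collapse = "")
}

hex_n_bits <- function(hex, n_bits) if (is.null(n_bits)) 4L * nchar(hex) else as.integer(n_bits)

hex_to_bits <- function(hex, n_bits = NULL) {
  vals <- strtoi(strsplit(tolower(hex), "")[[1]], base = 16L)
  if (anyNA(vals)) stop("invalid hex fingerprint string")
  bits <- as.vector(vapply(vals, function(v) as.integer(bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0L), integer(4L)))
  n <- hex_n_bits(hex, n_bits)
  bits[seq_len(n)]
}
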