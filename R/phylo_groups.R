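#' Cophenetic (path-length) distance matrix of a phylogenetic tree
#'
#' The distance between two leaves is the sum of branch lengths along the
#' tree path connecting them, in the tree's units (substitutions/site for
#' the maximum-likelihood trees this is designed for). Delegates to
#' [ape::cophenetic.phylo()] after validating the tree.
#'
#' @param tree An [ape::phylo] object (e.g. from [ape::read.tree()]).
#' @return Symmetric matrix over leaf labels with zero diagonal.
#' @export
cophenetic_matrix <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (length(tree$tip.label) < 2L) stop("tree needs at least 2 leaves")
  if (anyDuplicated(tree$tip.label)) stop("leaf ids must be unique")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree has missing branch lengths")
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Cut a hierarchy to maximise the number of major groups
#'
#' Agglomerative (complete-linkage) clustering of the cophenetic distance
#' matrix, cut at every k from 2 to `kmax`; for each cut the number of
#' "major" groups — those holding at least `min_fraction` of all leaves — is
#' counted, and the cut maximising that number is returned (smallest k on
#' ties). With the 1% default this is the rule used to define the
#' phylogenetic groups a BacCYP query is later assigned to: it resists the
#' long-tail of rogue leaves that fragment into sub-1% clusters at high k.
#'
#' @param d Distance matrix (e.g. from [cophenetic_matrix()]) or `dist`.
#' @param kmax Largest number of clusters to consider (clamped to n).
#' @param min_fraction Fraction of leaves a group needs to count as major.
#' @return A `grouping_result`: list with `k`, `labels` (leaf -> group
#'   letter), `fractions` (group -> leaf fraction), `n_major`, and the full
#'   `scan` (data.frame k, n_major).
#' @export
cut_by_one_percent_rule <- function(d, kmax = 30L, min_fraction = 0.01) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 leaves")
  kmax <- as.integer(min(kmax, n))
  if (kmax < 2L) stop("kmax must be at least 2")
  hc <- stats::hclust(stats::as.dist(dm), method = "complete")
  ks <- 2L:kmax
  n_major <- vapply(ks, function(k) {
    frac <- table(stats::cutree(hc, k = k)) / n
    sum(frac >= min_fraction)
  }, numeric(1))
  best_k <- ks[which.max(n_major)]  # which.max takes the first (smallest k) on ties
  cl <- stats::cutree(hc, k = best_k)
  labels <- group_letters(best_k)[cl]
  names(labels) <- names(cl)
  fractions <- table(labels) / n
  out <- list(k = best_k, labels = labels,
              fractions = stats::setNames(as.numeric(fractions), names(fractions)),
              n_major = sum(fractions >= min_fraction),
              scan = data.frame(k = ks, n_major = n_major))
  class(out) <- "grouping_result"
  out
}

#' @export
print.grouping_result <- function(x, ...) {
  cat("Phylogenetic grouping: k =", x$k, "clusters,", x$n_major,
      "major (>=1%) groups over", length(x$labels), "leaves\n")
  invisible(x)
}

group_letters <- function(k) {
  if (k <= 26L) return(LETTERS[seq_len(k)])
  c(LETTERS, as.vector(outer(LETTERS, LETTERS, paste0)))[seq_len(k)]
}

#' Assign a query sequence to a phylogenetic group
#'
#' Nearest-centroid classification over 3-mer composition: each reference
#' group's sequences are summarised by their mean k-mer count profile and the
#' query goes to the group whose centroid it is most cosine-similar to. This
#' is alignment-free and invariant to k-mer order, which makes it robust to
#' the rearrangement-free point divergence that separates the groups.
#'
#' @param query Amino-acid sequence (single string).
#' @param references Named character vector of reference sequences.
#' @param labels Group label per reference (named by reference id, or
#'   positional).
#' @param k k-mer size (default 3).
#' @return List with `group`, `score` (cosine to the winning centroid) and
#'   `margin` (score difference to the runner-up), plus all `scores`.
#' @export
assign_group <- function(query, references, labels, k = 3L) {
  if (length(references) == 0L) stop("no reference sequences")
  if (nchar(query) < k) stop("query shorter than k-mer size")
  if (!is.null(names(labels))) labels <- labels[names(references)]
  stopifnot(length(labels) == length(references))
  prof <- kmer_profile(query, k)
  ref_profs <- lapply(references, kmer_profile, k = k)
  keys <- sort(unique(c(names(prof), unlist(lapply(ref_profs, names)))))
  as_vec <- function(p) {
    v <- stats::setNames(numeric(length(keys)), keys)
    v[names(p)] <- p
    v
  }
  qv <- as_vec(prof)
  ref_mat <- vapply(ref_profs, as_vec, numeric(length(keys)))
  groups <- sort(unique(labels))
  scores <- vapply(groups, function(g) {
    centroid <- rowMeans(ref_mat[, labels == g, drop = FALSE])
    cosine_sim(qv, centroid)
  }, numeric(1))
  ord <- order(-scores)
  list(group = groups[ord[1L]], score = scores[ord[1L]],
       margin = if (length(scores) > 1L) scores[ord[1L]] - scores[ord[2L]] else NA_real_,
       scores = scores)
}

kmer_profile <- function(seq, k = 3L) {
  seq <- toupper(seq)
  n <- nchar(seq) - k + 1L
  kmers <- substring(seq, seq_len(n), seq_len(n) + k - 1L)
  tab <- table(kmers)
  stats::setNames(as.numeric(tab), names(tab))
}

cosine_sim <- function(a, b) {
  keys <- union(names(a), names(b))
  av <- stats::setNames(numeric(length(keys)), keys); av[names(a)] <- a
  bv <- stats::setNames(numeric(length(keys)), keys); bv[names(b)] <- b
  denom <- sqrt(sum(av^2)) * sqrt(sum(bv^2))
  if (denom == 0) return(0)
  sum(av * bv) / denom
}

# Motif patterns conserved across the BacCYP domain. "X" slots accept any
# residue letter including ambiguity codes; literal slots are exact. The
# heme motif's terminal G is relaxed to [G/A] (A is the group-N variant).
motif_patterns <- function() {
  x <- "[A-Z]"
  list(
    heme_binding = list(
      regex = paste0("F[GS]", x, "G", x, "[HR]", x, "C", x, "[GA]"),
      variant_pos = c(variant = 6L, terminal = 10L)),
    EXXR = list(regex = paste0("E", x, x, "R"), variant_pos = c()),
    proton_relay = list(
      regex = paste0("[AG]G", x, "[DE]T[TS]"),
      variant_pos = c(variant = 4L)),
    NRDP = list(regex = "[NH]RDP", variant_pos = c(variant = 1L))
  )
}

#' Scan a P450 domain sequence for conserved motifs
#'
#' Finds all non-overlapping matches of the four hallmark P450 motifs:
#' the cysteine heme-binding signature F-[G/S]-X-G-X-[H/R]-X-C-X-[G/A],
#' the E-X-X-R motif of the K-helix, the proton relay (acid-alcohol pair)
#' motif [A/G]-G-X-[D/E]-T-[T/S], and the [N/H]-R-D-P motif. Positions are
#' 1-based in the supplied sequence. The residue observed at each motif's
#' discriminating slot (H/R in the heme motif, D/E in the proton relay,
#' N/H in NRDP) is reported as a variant flag, since those residues separate
#' phylogenetic groups.
#'
#' @param domain_seq Amino-acid sequence (single string; case-insensitive).
#' @return data.frame with columns motif, start, end, match, variant
#'   (NA where the motif has no variant slot). Zero rows when nothing
#'   matches.
#' @export
scan_motifs <- function(domain_seq) {
  seq <- toupper(domain_seq)
  if (grepl("[^A-Z]", seq)) stop("sequence must contain only letters")
  hits <- lapply(names(motif_patterns()), function(nm) {
    pat <- motif_patterns()[[nm]]
    m <- gregexpr(pat$regex, seq)[[1]]
    if (m[1L] == -1L) return(NULL)
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    matches <- substring(seq, starts, starts + lens - 1L)
    variant <- if ("variant" %in% names(pat$variant_pos)) {
      substring(matches, pat$variant_pos[["variant"]], pat$variant_pos[["variant"]])
    } else NA_character_
    data.frame(motif = nm, start = starts, end = starts + lens - 1L,
               match = matches, variant = variant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(motif = character(0), start = integer(0), end = integer(0),
                      match = character(0), variant = character(0),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Group-diagnostic residue profile of the BacCYP domain
#'
#' Positions (in BacCYP domain numbering) whose conserved residue is
#' characteristic of one phylogenetic group. Groups A, D, E, F and N carry
#' no diagnostic residues.
#'
#' @return Named list: group letter -> named character vector of expected
#'   residues with domain positions as names (empty vector where the group
#'   has no diagnostics).
#' @export
baccyp_diagnostic_profile <- function() {
  res <- function(...) {
    v <- c(...)
    stats::setNames(substring(v, 1L, 1L), substring(v, 2L))
  }
  list(
    A = res(), B = res("L65", "W171", "E360"), C = res("P121", "T168"),
    D = res(), E = res(), F = res(),
    G = res("A128"), H = res("W155"),
    I = res("G116", "A128", "D149", "W155"),
    J = res("D121", "A128", "P144", "W155"),
    K = res("P131", "L132", "P133", "I137", "P144"),
    L = res("P131", "L132", "P133", "I137", "P144", "R149", "W155", "S156"),
    M = res("P162"), N = res()
  )
}

#' Check group-diagnostic residues in a domain-numbered sequence
#'
#' For each group in the profile, reports what fraction of its diagnostic
#' positions carry the expected residue in the query. The caller supplies
#' the mapping from domain numbering to query positions (from an alignment
#' to the domain reference); by default positions are taken at face value.
#'
#' @param domain_seq Amino-acid sequence.
#' @param profile Diagnostic profile as from [baccyp_diagnostic_profile()].
#' @param mapping Optional integer vector mapping domain position ->
#'   query position (NA = position not covered).
#' @return data.frame with group, n_diagnostics, n_checked, n_matched,
#'   fraction (NA for groups without diagnostics, flagged by
#'   `no_diagnostics`), and n_out_of_range.
#' @export
check_diagnostics <- function(domain_seq, profile = baccyp_diagnostic_profile(),
                              mapping = NULL) {
  seq <- toupper(domain_seq)
  chars <- strsplit(seq, "")[[1]]
  rows <- lapply(names(profile), function(g) {
    diag <- profile[[g]]
    if (length(diag) == 0L) {
      return(data.frame(group = g, n_diagnostics = 0L, n_checked = 0L,
                        n_matched = 0L, fraction = NA_real_,
                        no_diagnostics = TRUE, n_out_of_range = 0L))
    }
    pos <- as.integer(names(diag))
    qpos <- if (is.null(mapping)) pos else mapping[pos]
    in_range <- !is.na(qpos) & qpos >= 1L & qpos <= length(chars)
    matched <- in_range & chars[ifelse(in_range, qpos, 1L)] == diag
    data.frame(group = g, n_diagnostics = length(diag),
               n_checked = sum(in_range), n_matched = sum(matched),
               fraction = sum(matched) / length(diag),
               no_diagnostics = FALSE, n_out_of_range = sum(!in_range))
  })
  do.call(rbind, rows)
}

#' Percent identity between two sequences by global alignment
#'
#' Needleman-Wunsch global alignment (match +1, mismatch 0, linear gap -1
#' via [Biostrings::pairwiseAlignment()]); identity is the fraction of
#' matching columns over alignment columns, excluding terminal-gap columns
#' so that domain fragments are not penalised for missing ends.
#'
#' @param a,b Amino-acid sequences (single strings).
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    type = "global",
    substitutionMatrix = identity_submat(),
    gapOpening = 0, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  keep <- seq_along(pa)
  lead_a <- cumprod(pa == "-") > 0; lead_b <- cumprod(pb == "-") > 0
  trail_a <- rev(cumprod(rev(pa) == "-") > 0); trail_b <- rev(cumprod(rev(pb) == "-") > 0)
  keep <- !(lead_a | lead_b | trail_a | trail_b)
  if (sum(keep) == 0L) return(0)
  100 * sum(pa[keep] == pb[keep] & pa[keep] != "-") / sum(keep)
}

identity_submat <- function() {
  letters20 <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y","X","B","Z","*")
  m <- matrix(0, length(letters20), length(letters20),
              dimnames = list(letters20, letters20))
  diag(m) <- 1
  m
}

#' Stratify substrate-similarity values by protein sequence identity
#'
#' For pairs of proteins with known substrates, splits the substrate
#' Tanimoto similarities into strata: all pairs, same-phylogenetic-group
#' pairs (when labels are given), and pairs of highly similar proteins
#' (identity strictly above the threshold).
#'
#' @param pairs data.frame with columns `identity` (percent, 0-100) and `ti`
#'   (Tanimoto, 0-1); optional logical column `same_group`.
#' @param identity_threshold High-identity cut, strict (default 70: "over
#'   70%" excludes a pair at exactly 70).
#' @return List of numeric vectors `all`, `same_group` (NULL when no labels),
#'   `high_identity`.
#' @export
identity_vs_substrate_ti <- function(pairs, identity_threshold = 70) {
  stopifnot(all(c("identity", "ti") %in% names(pairs)))
  if (any(pairs$identity < 0 | pairs$identity > 100)) stop("identity must be in [0, 100]")
  if (any(pairs$ti < 0 | pairs$ti > 1)) stop("ti must be in [0, 1]")
  high <- pairs$ti[pairs$identity > identity_threshold]
  if (length(high) == 0L) warning("high-identity stratum is empty")
  list(all = pairs$ti,
       same_group = if ("same_group" %in% names(pairs)) pairs$ti[pairs$same_group] else NULL,
       high_identity = high)
}
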