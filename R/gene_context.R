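#' Load a genome annotation and gene-compound links
#'
#' Builds the genome model the neighbourhood search runs over. Gene records
#' come either from a GFF3 file (gene features; locus tag / ID attribute) or
#' from a TSV with columns `gene_id`, `contig`, `start`, `end`, `strand`
#' (1-based inclusive coordinates throughout). The links table attaches
#' annotated reaction compounds to genes: columns `gene_id`, `compound_id`,
#' `role` (one of "substrate"/"product"), optional `ec`.
#'
#' @param annotation Path to GFF3 (`.gff`/`.gff3`) or TSV, or a data.frame.
#' @param links Path to a links TSV or a data.frame.
#' @param library Optional `compound_library` used to flag link rows whose
#'   compound id is unknown.
#' @return A `genome_model`: list with `genes` (data.frame), `links`
#'   (data.frame) and `unknown_compounds` (character vector).
#' @export
load_annotations <- function(annotation, links, library = NULL) {
  genes <- if (is.data.frame(annotation)) {
    annotation
  } else if (grepl("\\.gff3?$", annotation, ignore.case = TRUE)) {
    read_gff_genes(annotation)
  } else {
    utils::read.delim(annotation, stringsAsFactors = FALSE)
  }
  req <- c("gene_id", "contig", "start", "end", "strand")
  if (!all(req %in% names(genes))) {
    stop("annotation needs columns: ", paste(setdiff(req, names(genes)), collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids in annotation")
  if (anyNA(genes$start) || anyNA(genes$end)) stop("missing gene coordinates")
  if (any(genes$start < 1L) || any(genes$end < genes$start)) {
    stop("invalid coordinates: need 1 <= start <= end")
  }
  links_df <- if (is.data.frame(links)) links else utils::read.delim(links, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "compound_id", "role") %in% names(links_df))) {
    stop("links need columns gene_id, compound_id, role")
  }
  if (!all(links_df$role %in% c("substrate", "product"))) {
    stop("link roles must be 'substrate' or 'product'")
  }
  unknown <- character(0)
  if (!is.null(library)) {
    unknown <- sort(unique(setdiff(links_df$compound_id, library$ids)))
    if (length(unknown)) {
      warning("links reference unknown compound ids: ", paste(unknown, collapse = ", "))
    }
  }
  model <- list(genes = genes[, req], links = links_df, unknown_compounds = unknown)
  class(model) <- "genome_model"
  model
}

read_gff_genes <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("package 'rtracklayer' is required to read GFF3")
  }
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type %in% c("gene", "CDS")]
  ids <- if (!is.null(gr$ID)) gr$ID else gr$locus_tag
  data.frame(gene_id = as.character(ids),
             contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Genomic neighbourhood of a target gene
#'
#' Neighbours are genes on the target's contig whose interval gap — the
#' number of base pairs strictly between the closest gene edges, zero for
#' overlapping or abutting genes (the [GenomicRanges::distance()]
#' convention) — is at most `max_gap_bp`. Strand is ignored for eligibility
#' (operon neighbours are reported whatever their orientation) but carried
#' through. The nearest gene on each side is flagged `adjacent`.
#'
#' @param model A `genome_model`.
#' @param target_id Gene id of the target BacCYP.
#' @param max_gap_bp Gap threshold in bp, inclusive (the classic expansion
#'   is 2000 bp).
#' @return A `neighborhood`: list with `target` (gene row) and `neighbors`
#'   (data.frame with gap_bp, side, adjacent flags), sorted by gap.
#' @export
neighbors <- function(model, target_id, max_gap_bp = 2000L) {
  stopifnot(inherits(model, "genome_model"), max_gap_bp >= 0L)
  genes <- model$genes
  ti <- match(target_id, genes$gene_id)
  if (is.na(ti)) stop("unknown target gene: ", target_id)
  target <- genes[ti, ]
  same <- genes[genes$contig == target$contig & genes$gene_id != target_id, , drop = FALSE]
  nb <- data.frame(gene_id = character(0), gap_bp = integer(0),
                   side = character(0), adjacent = logical(0),
                   strand = character(0), stringsAsFactors = FALSE)
  if (nrow(same) > 0L) {
    tgt_r <- GenomicRanges::GRanges(target$contig,
                                    IRanges::IRanges(target$start, target$end))
    oth_r <- GenomicRanges::GRanges(same$contig,
                                    IRanges::IRanges(same$start, same$end))
    gaps <- GenomicRanges::distance(tgt_r, oth_r)
    keep <- !is.na(gaps) & gaps <= max_gap_bp
    if (any(keep)) {
      kept <- same[keep, , drop = FALSE]
      mid_t <- (target$start + target$end) / 2
      side <- ifelse((kept$start + kept$end) / 2 < mid_t, "upstream", "downstream")
      nb <- data.frame(gene_id = kept$gene_id, gap_bp = as.integer(gaps[keep]),
                       side = side, adjacent = FALSE, strand = kept$strand,
                       stringsAsFactors = FALSE)
      for (s in c("upstream", "downstream")) {
        i <- which(nb$side == s)
        if (length(i)) nb$adjacent[i[which.min(nb$gap_bp[i])]] <- TRUE
      }
      nb <- nb[order(nb$gap_bp, nb$gene_id), ]
      rownames(nb) <- NULL
    }
  }
  out <- list(target = target, neighbors = nb, max_gap_bp = max_gap_bp)
  class(out) <- "neighborhood"
  out
}

#' @export
print.neighborhood <- function(x, ...) {
  cat("Neighborhood of", x$target$gene_id, "(gap <=", x$max_gap_bp, "bp):",
      nrow(x$neighbors), "neighbors\n")
  invisible(x)
}

#' Candidate substrates from the genomic context
#'
#' Pools the annotated reaction compounds (products and substrates) of all
#' neighbours. With a reference compound set, each candidate is scored by
#' its best Tanimoto similarity to the references and ranked by that score;
#' without one, candidates are ranked adjacent-first then by gap. At equal
#' score a neighbour's *product* outranks its *substrate* — in an operon
#' the upstream enzyme's product is the likelier P450 substrate.
#'
#' @param neighborhood A `neighborhood`.
#' @param model The `genome_model` providing the links.
#' @param library `compound_library` with fingerprints for TI scoring.
#' @param reference Optional character vector of reference compound ids.
#' @return A `context_prediction`: list with `status` ("ok" or
#'   "no-information") and `candidates` data.frame (compound_id,
#'   source_gene, role, gap_bp, adjacent, ti).
#' @export
context_candidates <- function(neighborhood, model, library, reference = NULL) {
  stopifnot(inherits(neighborhood, "neighborhood"))
  nb <- neighborhood$neighbors
  links <- model$links[model$links$gene_id %in% nb$gene_id, , drop = FALSE]
  links <- links[links$compound_id %in% library$ids, , drop = FALSE]
  if (nrow(links) == 0L) {
    out <- list(status = "no-information",
                candidates = data.frame(compound_id = character(0),
                                        source_gene = character(0),
                                        role = character(0), gap_bp = integer(0),
                                        adjacent = logical(0), ti = numeric(0)))
    class(out) <- "context_prediction"
    return(out)
  }
  cand <- data.frame(compound_id = links$compound_id, source_gene = links$gene_id,
                     role = links$role, stringsAsFactors = FALSE)
  # product annotations win when a (compound, source) pair carries both roles
  cand <- cand[order(cand$role != "product"), , drop = FALSE]
  cand <- cand[!duplicated(cand[, c("compound_id", "source_gene")]), , drop = FALSE]
  idx <- match(cand$source_gene, nb$gene_id)
  cand$gap_bp <- nb$gap_bp[idx]
  cand$adjacent <- nb$adjacent[idx]
  if (!is.null(reference) && length(reference) > 0L) {
    ref_fp <- library$fingerprints[intersect(reference, library$ids), , drop = FALSE]
    if (nrow(ref_fp) == 0L) stop("no reference compound found in library")
    cand$ti <- vapply(cand$compound_id, function(cid) {
      max(vapply(seq_len(nrow(ref_fp)), function(j) {
        tanimoto(library$fingerprints[cid, ], ref_fp[j, ])
      }, numeric(1)))
    }, numeric(1))
    ord <- order(-cand$ti, cand$role != "product", cand$gap_bp, cand$compound_id)
  } else {
    cand$ti <- NA_real_
    ord <- order(!cand$adjacent, cand$gap_bp, cand$role != "product", cand$compound_id)
  }
  cand <- cand[ord, , drop = FALSE]
  rownames(cand) <- NULL
  out <- list(status = "ok", candidates = cand)
  class(out) <- "context_prediction"
  out
}

#' @export
print.context_prediction <- function(x, ...) {
  if (x$status == "no-information") {
    cat("Context prediction: no annotated neighbor compounds\n")
  } else {
    cat("Context prediction:", nrow(x$candidates), "candidates; top:",
        x$candidates$compound_id[1L], "\n")
  }
  invisible(x)
}

#' Recovery rate of planted substrates from genomic context
#'
#' Fraction of targets whose rank-1 context candidate matches the true
#' substrate at TI >= `ti_success`. Targets with no informative context
#' ("no-information" predictions) are excluded from the denominator,
#' matching the convention of scoring only cases where results are
#' identified.
#'
#' @param predictions Named list of `context_prediction` objects (names =
#'   target gene ids).
#' @param truth Named character vector: target gene id -> true substrate
#'   compound id.
#' @param library `compound_library` for TI computation.
#' @param ti_success Success threshold on TI between rank-1 candidate and
#'   truth (default 0.85; "precise" retrieval means near-identity).
#' @return List with `recovery` (NA when no target is informative),
#'   `n_informative`, `n_total`, `n_success`.
#' @export
context_recovery <- function(predictions, truth, library, ti_success = 0.85) {
  ids <- names(predictions)
  if (is.null(ids) || !all(ids %in% names(truth))) {
    stop("every prediction needs a truth entry")
  }
  informative <- vapply(predictions, function(p) p$status == "ok", logical(1))
  n_inf <- sum(informative)
  if (n_inf == 0L) {
    return(list(recovery = NA_real_, n_informative = 0L,
                n_total = length(ids), n_success = 0L))
  }
  succ <- vapply(ids[informative], function(tid) {
    top <- predictions[[tid]]$candidates$compound_id[1L]
    ti <- tanimoto(library$fingerprints[top, ], library$fingerprints[truth[[tid]], ])
    ti >= ti_success
  }, logical(1))
  list(recovery = mean(succ), n_informative = n_inf,
       n_total = length(ids), n_success = sum(succ))
}
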