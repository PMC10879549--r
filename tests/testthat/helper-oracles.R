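# Independent reference implementations used to cross-check the package.
# These are deliberately naive (loops, exhaustive scans, generic numeric
# optimisation) and share no code with the implementations they check.

# Sphere-exclusion clustering, written as a plain repeated scan over the
# matrix: at each round recount every unassigned compound's unassigned
# neighbours, pick the top (ties: lexicographically smallest id), carve out
# its sphere.
oracle_sphere_exclusion <- function(sim, cutoff) {
  ids <- rownames(sim)
  unassigned <- ids
  clusters <- list()
  while (length(unassigned) > 0L) {
    counts <- sapply(unassigned, function(i) {
      sum(vapply(setdiff(unassigned, i), function(j) sim[i, j] >= cutoff,
                 logical(1)))
    })
    top <- unassigned[counts == max(counts)]
    centroid <- sort(top)[1L]
    members <- c(centroid,
                 Filter(function(j) sim[centroid, j] >= cutoff,
                        setdiff(unassigned, centroid)))
    clusters[[length(clusters) + 1L]] <- sort(members)
    unassigned <- setdiff(unassigned, members)
  }
  clusters
}

butina_as_sets <- function(cl) {
  unname(lapply(split(names(cl$labels), cl$labels), function(x) sort(x)))
}

same_partition <- function(a, b) {
  norm <- function(p) sort(vapply(p, paste, "", collapse = ","))
  identical(norm(a), norm(b))
}

# Random symmetric similarity matrix with unit diagonal.
random_sim_matrix <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(sprintf("c%02d", seq_len(n)), sprintf("c%02d", seq_len(n)))
  m
}

# Leaf-to-leaf tree distances by explicit root-path tracing: distance =
# depth(i) + depth(j) - 2 * depth(deepest shared ancestor).
oracle_tree_distances <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen[tree$edge[, 2L]] <- tree$edge.length
  path_to_root <- function(node) {
    nodes <- node
    while (node != root) {
      node <- parent[node]
      nodes <- c(nodes, node)
    }
    nodes
  }
  depth <- function(node) {
    total <- 0
    while (node != root) {
      total <- total + elen[node]
      node <- parent[node]
    }
    total
  }
  d <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip - 1L)) {
    pi <- path_to_root(i)
    for (j in (i + 1L):ntip) {
      pj <- path_to_root(j)
      mrca <- intersect(pi, pj)[1L]
      d[i, j] <- d[j, i] <- depth(i) + depth(j) - 2 * depth(mrca)
    }
  }
  d
}

# Exhaustive scan of the one-percent rule over all candidate k.
oracle_major_group_scan <- function(d, kmax, min_fraction = 0.01) {
  dm <- as.matrix(d)
  hc <- stats::hclust(stats::as.dist(dm), method = "complete")
  ks <- 2:min(kmax, nrow(dm))
  vapply(ks, function(k) {
    sum(table(stats::cutree(hc, k = k)) / nrow(dm) >= min_fraction)
  }, numeric(1))
}

# Minimum RMSD over rigid motions found by generic numeric optimisation of
# Euler angles (translation handled by centering), from several starts.
oracle_min_rmsd <- function(mobile, reference) {
  m0 <- scale(mobile, scale = FALSE)
  r0 <- scale(reference, scale = FALSE)
  rot_from_angles <- function(a) {
    cx <- cos(a[1]); sx <- sin(a[1])
    cy <- cos(a[2]); sy <- sin(a[2])
    cz <- cos(a[3]); sz <- sin(a[3])
    rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    rz %*% ry %*% rx
  }
  obj <- function(a) {
    sqrt(mean(rowSums((m0 %*% t(rot_from_angles(a)) - r0)^2)))
  }
  starts <- as.matrix(expand.grid(a1 = c(0, pi / 2, pi, 3 * pi / 2),
                                  a2 = c(0, pi / 2, pi),
                                  a3 = c(0, pi / 2, pi, 3 * pi / 2)))
  best <- Inf
  for (s in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, fit$value)
  }
  best
}

# Small genome fixture shared by the gene-context tests: a target with
# neighbours at controlled gaps.
toy_genome <- function() {
  genes <- data.frame(
    gene_id = c("tgt", "overlap", "near", "edge_in", "edge_out", "other_ctg"),
    contig = c("c1", "c1", "c1", "c1", "c1", "c2"),
    start = c(10000L, 10500L, 12001L, 13999L, 16001L, 1000L),
    end = c(11000L, 11500L, 12500L, 14500L, 16500L, 1500L),
    strand = c("+", "+", "-", "+", "+", "+"),
    stringsAsFactors = FALSE)
  # gaps to tgt [10000,11000]: overlap 0, near 1000, edge_in 2998, edge_out 5000
  links <- data.frame(
    gene_id = c("overlap", "near", "near"),
    compound_id = c("cpdA", "cpdB", "cpdC"),
    role = c("product", "product", "substrate"),
    stringsAsFactors = FALSE)
  list(genes = genes, links = links)
}

toy_library <- function() {
  fps <- rbind(
    cpdA = c(1, 1, 1, 1, 0, 0, 0, 0),
    cpdB = c(1, 1, 1, 0, 1, 0, 0, 0),
    cpdC = c(0, 0, 0, 0, 1, 1, 1, 1),
    cpdD = c(1, 1, 1, 1, 1, 0, 0, 0))
  compound_library(rownames(fps), fps,
                   groups = c("g1", "g1", "g2", "g1"))
}
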