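#' Estimate tumor purity from the somatic VAF mode
#'
#' For clonal heterozygous mutations in copy-neutral regions the expected
#' VAF is purity/2, so purity is estimated as twice the mode of the
#' filtered VAF distribution. The mode is located by Gaussian kernel
#' density (bandwidth 0.03) on [0.02, 1]; the lower bound keeps noise
#' calls near zero from dominating. When segments are supplied only
#' variants in total copy number 2 regions are used.
#'
#' @param variants a `somatic_variants` table
#' @param segments optional `allelic_segments` for the copy-neutral filter
#' @param min_depth minimum depth per variant, default 30
#' @param min_variants minimum number of usable SNVs, default 50
#' @param bandwidth kernel bandwidth, default 0.03
#' @return purity estimate in (0, 1]
#' @export
estimate_purity <- function(variants, segments = NULL, min_depth = 30,
                            min_variants = 50, bandwidth = 0.03) {
  v <- variants[variants$vclass == "SNP" & !is.na(variants$depth) &
                  variants$depth >= min_depth, , drop = FALSE]
  if (!is.null(segments) && nrow(segments) > 0) {
    cn <- local_total_cn(v$chrom, v$pos, segments)
    v <- v[!is.na(cn) & cn == 2L, , drop = FALSE]
  }
  vaf <- v$vaf[v$vaf >= 0.02 & v$vaf <= 1]
  if (length(vaf) < min_variants)
    stop("insufficient variants for purity (", length(vaf), " < ",
         min_variants, ")")
  d <- stats::density(vaf, bw = bandwidth, from = 0.02, to = 1, n = 512)
  min(1, 2 * d$x[which.max(d$y)])
}

#' Total copy number at variant positions
#' @keywords internal
local_total_cn <- function(chrom, pos, segments) {
  out <- rep(NA_integer_, length(chrom))
  sg <- as.data.frame(segments)
  for (cc in unique(chrom)) {
    s <- sg[sg$chrom == cc, , drop = FALSE]
    if (nrow(s) == 0) next
    sel <- which(chrom == cc)
    idx <- findInterval(pos[sel], s$start_bp)
    hit <- idx >= 1 & pos[sel] <= s$end_bp[pmax(idx, 1)]
    out[sel[hit]] <- s$total_cn[idx[hit]]
  }
  out
}

#' Build a presence/absence panel over matched samples
#'
#' A mutation counts as detected in a sample when its VAF and depth clear
#' the detection thresholds. The mutation universe is the union of
#' detected mutations over all samples; the panel carries the
#' sample-by-mutation presence matrix plus per-mutation VAF and depth.
#'
#' @param samples list of `sample_profile` from one patient (>= 2)
#' @param detect_vaf minimum VAF for detection, default 0.05
#' @param detect_depth minimum depth for detection, default 10
#' @return list of class `lineage_panel`: samples, mutation_universe,
#'   presence (logical matrix), vaf (numeric matrix)
#' @export
build_panel <- function(samples, detect_vaf = 0.05, detect_depth = 10) {
  if (length(samples) < 2) stop("a panel needs at least 2 samples")
  ids <- vapply(samples, function(s) s$sample_id, "")
  names(samples) <- ids
  detected <- lapply(samples, function(s) {
    v <- s$variants
    v[!is.na(v$vaf) & v$vaf >= detect_vaf &
        !is.na(v$depth) & v$depth >= detect_depth, , drop = FALSE]
  })
  universe <- sort(unique(unlist(lapply(detected, function(v) v$id))))
  presence <- matrix(FALSE, length(ids), length(universe),
                     dimnames = list(ids, universe))
  vafm <- matrix(0, length(ids), length(universe),
                 dimnames = list(ids, universe))
  for (s in ids) {
    v <- detected[[s]]
    presence[s, v$id] <- TRUE
    vafm[s, v$id] <- v$vaf
  }
  structure(list(samples = samples, mutation_universe = universe,
                 presence = presence, vaf = vafm,
                 detect_vaf = detect_vaf, detect_depth = detect_depth),
            class = "lineage_panel")
}

#' Euler-region counts of a panel
#'
#' Counts mutations by presence/absence pattern across the panel's
#' samples (the regions of an Euler diagram). Pattern labels join the
#' sorted names of the samples carrying the mutation with `&`. Counts
#' always sum to the universe size.
#'
#' @param panel a `lineage_panel`
#' @return named integer vector of region counts
#' @export
euler_regions <- function(panel) {
  if (length(panel$mutation_universe) == 0) return(stats::setNames(integer(), character()))
  pat <- apply(panel$presence, 2, function(col)
    paste(sort(rownames(panel$presence)[col]), collapse = "&"))
  tab <- table(pat)
  stats::setNames(as.integer(tab), names(tab))
}

#' Cellular prevalence of a mutation
#'
#' Closed-form prevalence under mutation multiplicity 1:
#' `cp = vaf * (purity * total_cn + (1 - purity) * 2) / purity`,
#' clamped to [0, 1]. At purity 1 on diploid copy number this is simply
#' twice the VAF.
#'
#' @param vaf variant allele fraction
#' @param purity tumor purity in (0, 1]
#' @param local_total_cn total copy number at the locus (>= 1)
#' @return prevalence in [0, 1]
#' @export
cellular_prevalence <- function(vaf, purity, local_total_cn = 2) {
  if (any(purity <= 0)) stop("purity must be positive")
  if (any(local_total_cn < 1)) stop("local_total_cn must be >= 1")
  pmin(1, pmax(0, vaf * (purity * local_total_cn + (1 - purity) * 2) / purity))
}

#' Cluster mutations by cellular-prevalence profile
#'
#' Every mutation in the panel universe gets a per-sample cellular
#' prevalence vector (0 where undetected: absence is the signal that
#' separates lineage-private clones). Profiles are clustered by k-means
#' over k = 1..k_max with seeded restarts; k is chosen by maximum mean
#' silhouette width, with k = 1 reserved for panels whose total profile
#' variance falls below `variance_floor`. Clusters holding at least
#' `min_fraction` of all substitutions are the "top" clusters; smaller
#' ones are kept but flagged minor.
#'
#' @param panel a `lineage_panel`
#' @param purities named purity per sample (defaults to the profiles'
#'   purity, then 1)
#' @param min_fraction top-cluster rule, default 0.05
#' @param k_max maximum number of clusters, default 8
#' @param restarts k-means restarts, default 10
#' @param seed RNG seed for k-means, default 20
#' @param variance_floor total-variance floor under which k = 1, default 0.001
#' @return list of class `clone_clusters`: data.frame `clusters`
#'   (cluster_id, n_members, fraction, minor, one prevalence column per
#'   sample) and `assignment` (mutation id -> cluster_id)
#' @export
cluster_prevalences <- function(panel, purities = NULL, min_fraction = 0.05,
                                k_max = 8, restarts = 10, seed = 20,
                                variance_floor = 0.001) {
  uni <- panel$mutation_universe
  if (length(uni) < 20) stop("too few mutations to cluster (need >= 20)")
  ids <- rownames(panel$presence)
  if (is.null(purities)) {
    purities <- vapply(panel$samples, function(s)
      ifelse(is.na(s$purity), 1, s$purity), 1)[ids]
  }
  cp <- panel$vaf
  for (s in ids) {
    segs <- panel$samples[[s]]$segments
    cn <- if (nrow(segs) > 0) {
      v <- panel$samples[[s]]$variants
      loc <- local_total_cn(v$chrom, v$pos, segs)
      cnv <- stats::setNames(loc, v$id)
      out <- cnv[colnames(cp)]
      out[is.na(out)] <- 2L
      out
    } else rep(2L, ncol(cp))
    cp[s, ] <- cellular_prevalence(cp[s, ], purities[s], pmax(1, cn))
  }
  x <- t(cp)  # mutations x samples

  rng <- local_rng(seed)
  on.exit(rng())
  totvar <- sum(apply(x, 2, stats::var))
  k_best <- 1L
  if (totvar >= variance_floor) {
    k_hi <- min(k_max, nrow(unique(x)) - 1L)
    sil <- rep(-Inf, max(2, k_hi))
    fits <- list()
    for (k in 2:max(2, k_hi)) {
      fits[[k]] <- stats::kmeans(x, centers = k, nstart = restarts,
                                 iter.max = 50)
      d <- cluster::silhouette(fits[[k]]$cluster, stats::dist(x))
      sil[k] <- mean(d[, "sil_width"])
    }
    k_best <- which.max(sil)
  }
  assign <- if (k_best == 1L) rep(1L, nrow(x)) else fits[[k_best]]$cluster

  # order clusters by size, relabel 1..k
  sizes <- sort(table(assign), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  assign <- as.integer(relabel[as.character(assign)])
  rows <- lapply(seq_along(sizes), function(k) {
    members <- assign == k
    prev <- colMeans(x[members, , drop = FALSE])
    cbind(data.frame(cluster_id = k, n_members = sum(members),
                     fraction = mean(members),
                     minor = mean(members) < min_fraction),
          as.data.frame(as.list(prev)))
  })
  clusters <- do.call(rbind, rows)
  structure(list(clusters = clusters,
                 assignment = stats::setNames(assign, rownames(x)),
                 sample_ids = ids, min_fraction = min_fraction,
                 k = as.integer(max(assign))),
            class = "clone_clusters")
}

#' Top clusters (those meeting the minimum-fraction rule)
#' @param clusters a `clone_clusters`
#' @return subset of the cluster table with `minor == FALSE`
#' @export
top_clusters <- function(clusters) {
  clusters$clusters[!clusters$clusters$minor, , drop = FALSE]
}

#' Infer clone trees consistent with the prevalence sum rule
#'
#' Enumerates all rooted trees over the clusters (root fixed to the
#' cluster whose prevalence is maximal in every sample) and keeps those
#' satisfying, in every sample, that the prevalences of each parent's
#' children sum to at most the parent's prevalence plus `tolerance`.
#' Trees are returned ordered by total slack (the summed unused parent
#' prevalence), tightest first.
#'
#' @param clusters a `clone_clusters` (use [top_clusters()] membership
#'   when minor clusters should be excluded); at most 8 clusters
#' @param tolerance sum-rule slack per (sample, parent), default 0.05
#' @param include_minor include minor clusters, default FALSE
#' @return list of class `clone_tree` objects: each has `edges`
#'   (data.frame parent -> child), `root`, `slack`
#' @export
infer_clone_tree <- function(clusters, tolerance = 0.05,
                             include_minor = FALSE) {
  tab <- clusters$clusters
  if (!include_minor) tab <- tab[!tab$minor, , drop = FALSE]
  ids <- tab$cluster_id
  n <- length(ids)
  if (n > 8) stop("tree enumeration supports at most 8 clusters")
  prev <- as.matrix(tab[, clusters$sample_ids, drop = FALSE])
  rownames(prev) <- ids

  root_candidates <- ids[apply(prev, 1, function(p)
    all(p >= apply(prev, 2, max) - 1e-9))]
  if (length(root_candidates) == 0)
    stop("no valid root: no cluster dominates in all samples")
  root <- root_candidates[1]
  if (n == 1)
    return(list(structure(list(edges = data.frame(parent = integer(),
                                                  child = integer()),
                               root = root, slack = 0),
                          class = "clone_tree")))

  nonroot <- setdiff(ids, root)
  choice <- lapply(nonroot, function(i) setdiff(ids, i))
  grid <- do.call(expand.grid, c(choice, list(KEEP.OUT.ATTRS = FALSE)))
  names(grid) <- as.character(nonroot)

  trees <- list()
  for (r in seq_len(nrow(grid))) {
    parent <- stats::setNames(as.integer(unlist(grid[r, ])), names(grid))
    # acyclicity: walk each node to the root
    ok <- TRUE
    for (v in nonroot) {
      seen <- character(); cur <- as.character(v)
      while (cur != as.character(root)) {
        if (cur %in% seen || !(cur %in% names(parent))) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- as.character(parent[cur])
      }
      if (!ok) break
    }
    if (!ok) next
    # sum rule in every sample
    slack <- 0
    for (p in ids) {
      kids <- as.integer(names(parent)[parent == p])
      if (length(kids) == 0) next
      for (s in seq_len(ncol(prev))) {
        excess <- sum(prev[as.character(kids), s]) - prev[as.character(p), s]
        if (excess > tolerance) { ok <- FALSE; break }
        slack <- slack + max(0, -excess)
      }
      if (!ok) break
    }
    if (!ok) next
    trees[[length(trees) + 1]] <- structure(
      list(edges = data.frame(parent = unname(parent),
                              child = as.integer(names(parent))),
           root = root, slack = slack),
      class = "clone_tree")
  }
  trees[order(vapply(trees, function(t) t$slack, 1))]
}

#' Re-validate a clone tree's sum rule against cluster prevalences
#' @param tree a `clone_tree`
#' @param clusters the `clone_clusters` it was inferred from
#' @param tolerance slack used at inference
#' @return TRUE when every (sample, parent) satisfies the sum rule
#' @export
validate_clone_tree <- function(tree, clusters, tolerance = 0.05) {
  tab <- clusters$clusters
  prev <- as.matrix(tab[, clusters$sample_ids, drop = FALSE])
  rownames(prev) <- tab$cluster_id
  for (p in unique(tree$edges$parent)) {
    kids <- tree$edges$child[tree$edges$parent == p]
    for (s in seq_len(ncol(prev)))
      if (sum(prev[as.character(kids), s]) >
          prev[as.character(p), s] + tolerance + 1e-12)
        return(FALSE)
  }
  TRUE
}
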