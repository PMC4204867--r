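#' Cluster motor patterns
#'
#' Two modes mirror the two articulatory families: `"motor_kmeans"` runs
#' Lloyd's K-means on the serialized (zero-padded 93-element) motor
#' vectors, which suits plosive closures; `"acoustic_dtw"` clusters the
#' synthesized outputs with a K-medoids partition (PAM) under the DTW
#' metric, which suits vocalic and fricative sounds. Every pattern is
#' assigned to exactly one cluster and each cluster reports an exemplar
#' (the pattern nearest the center, or the medoid).
#'
#' @param patterns list of [MotorPattern-class] objects.
#' @param mode "motor_kmeans" or "acoustic_dtw".
#' @param k number of clusters (<= number of patterns).
#' @param seed RNG seed.
#' @param config a [DiscoveryConfig-class] (needed to synthesize
#'   representations in acoustic mode).
#' @param features optional precomputed `patternFeatures()` list, parallel
#'   to `patterns`.
#' @return list with `assignments` (integer per pattern), `exemplars`
#'   (indices into `patterns`), `k`, `mode`.
#' @export
clusterPatterns <- function(patterns, mode = c("motor_kmeans", "acoustic_dtw"),
                            k, seed = 1L, config = discoveryConfig(),
                            features = NULL) {
  mode <- match.arg(mode)
  n <- length(patterns)
  if (k > n) stop("k (", k, ") exceeds the number of patterns (", n, ")")
  if (k == n) {
    return(list(assignments = seq_len(n), exemplars = seq_len(n), k = k,
                mode = mode))
  }
  set.seed(seed)
  if (mode == "motor_kmeans") {
    X <- t(vapply(patterns, serializePattern, numeric(93L)))
    km <- stats::kmeans(X, centers = k, algorithm = "Lloyd",
                        nstart = 5, iter.max = 100)
    exemplars <- vapply(seq_len(k), function(c) {
      members <- which(km$cluster == c)
      d <- rowSums((X[members, , drop = FALSE] -
                      matrix(km$centers[c, ], length(members), ncol(X),
                             byrow = TRUE))^2)
      members[which.min(d)]
    }, integer(1))
    list(assignments = as.integer(km$cluster), exemplars = exemplars,
         k = k, mode = mode)
  } else {
    if (is.null(features))
      features <- lapply(patterns, patternFeatures, config = config)
    reps <- lapply(features, `[[`, "rep")
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- dtwDistance(reps[[i]], reps[[j]])
    }
    pm <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE)
    list(assignments = as.integer(pm$clustering),
         exemplars = as.integer(pm$id.med), k = k, mode = mode)
  }
}

#' Generate composite (multi-gesture) motor patterns
#'
#' Expands a single-articulation inventory into the composite token
#' families CV (CvV, CuV, FvV, FuV, NV), VC (VCv, VCu, VFv, VFu, VN) and
#' VV, where Cv/Cu are voiced/voiceless plosives, Fv/Fu voiced/voiceless
#' fricatives, N nasals and V vowels. VV pairs are ordered and exclude
#' self-pairs (a doubled identical vowel is not a diphthong-like token).
#' Each composite stays within the 3-sub-pattern cap since all inputs are
#' single-target patterns. A missing category class skips its families
#' with a warning.
#'
#' @param inventory list of single-articulation [MotorPattern-class]
#'   objects.
#' @param gap inter-gesture gap, s.
#' @return list of composite [MotorPattern-class] objects.
#' @export
generateComposites <- function(inventory, gap = 0.02) {
  classOf <- function(p) {
    switch(p@category,
           vowel = "V",
           nasal = "N",
           plosive = if (p@voiced) "Cv" else "Cu",
           fricative = if (p@voiced) "Fv" else "Fu",
           "other")
  }
  classes <- split(inventory, vapply(inventory, classOf, character(1)))
  V <- classes[["V"]] %||% list()
  out <- list()
  consClasses <- c("Cv", "Cu", "Fv", "Fu", "N")
  if (length(V) == 0L) {
    warning("no vowels in inventory; no composites generated")
    return(out)
  }
  for (cc in consClasses) {
    cons <- classes[[cc]] %||% list()
    if (length(cons) == 0L) {
      warning("no patterns of class ", cc,
              "; skipping its CV and VC families")
      next
    }
    for (c1 in cons) for (v in V) {
      out[[length(out) + 1L]] <- concatenatePatterns(c1, v, gap)
      out[[length(out) + 1L]] <- concatenatePatterns(v, c1, gap)
    }
  }
  for (v1 in V) for (v2 in V) {
    if (!identical(v1@id, v2@id))
      out[[length(out) + 1L]] <- concatenatePatterns(v1, v2, gap)
  }
  out
}
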