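# Transcription coding, archiphoneme consolidation, dataset comparison and
# the two-proportion z-test machinery.

#' Load an archiphoneme consolidation table
#'
#' The shipped tables map every SAMPA phoneme of English, German and French
#' transcriptions to one archiphoneme category (pipe notation, e.g. `|pb|`
#' covering /p/ and /b/), including the onset-fused vowel variants (e.g.
#' /ja/, /ra/, /la/ fold into the same vowel archiphoneme as /a/), so that
#' responses can be compared across languages.
#'
#' @param language "English", "German" or "French".
#' @param path optional CSV (columns language, phoneme, archiphoneme)
#'   replacing the shipped table.
#' @return an [ArchiphonemeTable-class].
#' @examples
#' tab <- archiphonemeTable("English")
#' consolidatePhoneme("p", tab)
#' @export
archiphonemeTable <- function(language = c("English", "German", "French"),
                              path = NULL) {
  language <- match.arg(language)
  if (is.null(path))
    path <- system.file("extdata", "archiphonemes.csv",
                        package = "vocalearn", mustWork = TRUE)
  tab <- utils::read.csv(path)
  tab <- tab[tab$language == language, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no rows for language ", language)
  new("ArchiphonemeTable", language = language,
      mapping = stats::setNames(tab$archiphoneme, tab$phoneme))
}

#' Vowel archiphoneme categories
#'
#' The five vowel archiphonemes; all other archiphonemes are consonantal.
#' Used to assign parsed phonemes to the C1 V1 V2 C2 slots.
#' @export
vowelArchiphonemes <- function() c("|ie|", "|A|", "|O|", "|UV|", "|&|")

#' Parse a raw transcription code
#'
#' The coding scheme: `#` codes a silent response, `xxx` an
#' untranscribable one (typically attempted mimicry), and otherwise a
#' comma-separated list of SAMPA phonemes within a CVC or CVV frame with
#' empty slots coded by an empty field. Codes longer than three elements
#' keep only the first three (responses beyond CVC/CVV treated as
#' precocious idioms). Slot assignment (C1 V1 V2 C2) classifies each
#' phoneme as vowel or consonant via the consolidation table.
#'
#' @param raw the raw code string, e.g. `"b,A"`, `"#"`, `"xxx"`,
#'   `"h,@,l"`.
#' @param tokenId token identifier.
#' @param table an [ArchiphonemeTable-class] used to classify phonemes as
#'   vowels or consonants.
#' @return a [TranscriptionRecord-class].
#' @examples
#' parseCoding("b,A", "t1", archiphonemeTable("English"))
#' @export
parseCoding <- function(raw, tokenId = "token", table) {
  raw <- trimws(raw)
  if (raw == "#")
    return(new("TranscriptionRecord", tokenId = tokenId, kind = "silent",
               c1 = "", v1 = "", v2 = "", c2 = ""))
  if (raw == "xxx")
    return(new("TranscriptionRecord", tokenId = tokenId,
               kind = "untranscribable", c1 = "", v1 = "", v2 = "", c2 = ""))
  parts <- trimws(strsplit(raw, ",", fixed = TRUE)[[1]])
  parts <- parts[parts != ""]
  if (length(parts) == 0L)
    stop("malformed code '", raw, "': no phonemes at position 1")
  if (length(parts) > 3L) parts <- parts[1:3]
  isV <- vapply(seq_along(parts), function(i) {
    ph <- parts[i]
    arch <- table@mapping[ph]
    if (is.na(arch))
      stop("malformed code '", raw, "': unknown phoneme '", ph,
           "' at position ", i)
    arch %in% vowelArchiphonemes()
  }, logical(1))
  c1 <- v1 <- v2 <- c2 <- ""
  for (i in seq_along(parts)) {
    if (isV[i]) {
      if (v1 == "") v1 <- parts[i]
      else if (v2 == "") v2 <- parts[i]
      else stop("malformed code '", raw, "': third vowel at position ", i)
    } else {
      if (v1 == "" && c1 == "") c1 <- parts[i]
      else if (c2 == "") c2 <- parts[i]
      else stop("malformed code '", raw, "': extra consonant at position ", i)
    }
  }
  new("TranscriptionRecord", tokenId = tokenId, kind = "coded",
      c1 = c1, v1 = v1, v2 = v2, c2 = c2)
}

#' Consolidate a record (or a single phoneme) to archiphonemes
#'
#' Each non-empty slot is mapped through the language's consolidation
#' table; empty slots become the `#` placeholder. A phoneme missing from
#' the table is an error naming the phoneme and language.
#'
#' @param record a [TranscriptionRecord-class].
#' @param table an [ArchiphonemeTable-class].
#' @return named character c(C1, V1, V2, C2) of archiphoneme labels (`#`
#'   for empty slots; all `#` for silent/untranscribable records).
#' @export
consolidate <- function(record, table) {
  slotVals <- c(C1 = record@c1, V1 = record@v1, V2 = record@v2,
                C2 = record@c2)
  vapply(slotVals, function(ph) {
    if (ph == "") return("#")
    consolidatePhoneme(ph, table)
  }, character(1))
}

#' @rdname consolidate
#' @param phoneme a single SAMPA phoneme string.
#' @export
consolidatePhoneme <- function(phoneme, table) {
  arch <- table@mapping[phoneme]
  if (is.na(arch))
    stop("phoneme '", phoneme, "' is not in the ", table@language,
         " consolidation table")
  unname(arch)
}

#' Consolidate a whole coded dataset
#'
#' @param codes data.frame with columns `tokenId` and `raw`.
#' @param table an [ArchiphonemeTable-class].
#' @return data.frame with tokenId, kind and archiphoneme columns C1, V1,
#'   V2, C2 (`#` marks an absent slot; silent and untranscribable records
#'   get NA labels).
#' @export
consolidateDataset <- function(codes, table) {
  rows <- lapply(seq_len(nrow(codes)), function(i) {
    rec <- parseCoding(codes$raw[i], codes$tokenId[i], table)
    lab <- if (rec@kind == "coded") consolidate(rec, table)
           else c(C1 = NA, V1 = NA, V2 = NA, C2 = NA)
    data.frame(tokenId = rec@tokenId, kind = rec@kind,
               C1 = lab[["C1"]], V1 = lab[["V1"]], V2 = lab[["V2"]],
               C2 = lab[["C2"]])
  })
  do.call(rbind, rows)
}

#' Pairwise comparison of two labelled datasets
#'
#' For every token labelled in both datasets the two archiphoneme labels
#' of the chosen slot are compared: an identical pair increments that
#' archiphoneme's same-label counter, a differing pair increments the
#' counter of the unordered label pair. Tokens missing a label (NA) in
#' either dataset are tallied as skipped.
#'
#' @param a,b data.frames with a `tokenId` column and the slot column
#'   (e.g. from [consolidateDataset()]); they must share the same token-id
#'   universe.
#' @param slot which slot to compare ("C1" or "V1" in the study; any slot
#'   column works).
#' @return a [ComparisonResult-class].
#' @export
compareDatasets <- function(a, b, slot = c("V1", "C1", "V2", "C2")) {
  slot <- match.arg(slot)
  if (!length(intersect(a$tokenId, b$tokenId)))
    stop("datasets share no token ids")
  m <- merge(a[, c("tokenId", slot)], b[, c("tokenId", slot)],
             by = "tokenId", suffixes = c(".a", ".b"))
  la <- m[[paste0(slot, ".a")]]
  lb <- m[[paste0(slot, ".b")]]
  ok <- !is.na(la) & !is.na(lb)
  skipped <- sum(!ok)
  la <- la[ok]; lb <- lb[ok]
  same <- la == lb
  sameCounts <- if (any(same)) table(la[same]) else integer()
  diffKeys <- if (any(!same)) {
    apply(cbind(la[!same], lb[!same]), 1,
          function(p) paste(sort(p), collapse = "|"))
  } else character()
  diffCounts <- if (length(diffKeys)) table(diffKeys) else integer()
  new("ComparisonResult",
      sameCounts = stats::setNames(as.numeric(sameCounts), names(sameCounts)),
      diffCounts = stats::setNames(as.numeric(diffCounts), names(diffCounts)),
      totalSame = sum(same), totalDifferent = sum(!same),
      skipped = skipped, slot = slot)
}

#' Sum a group of comparison results
#'
#' Element-wise summation of the same/different count maps over multiple
#' pairwise comparisons, giving a single result for a dataset group (e.g.
#' all English-German session pairs).
#'
#' @param results list of [ComparisonResult-class] objects.
#' @return a combined [ComparisonResult-class].
#' @export
sumGroupComparisons <- function(results) {
  stopifnot(length(results) >= 1L)
  addMaps <- function(x, y) {
    keys <- union(names(x), names(y))
    stats::setNames(vapply(keys, function(k)
      (x[k] %|0|% 0) + (y[k] %|0|% 0), numeric(1)), keys)
  }
  same <- results[[1]]@sameCounts
  diff <- results[[1]]@diffCounts
  skipped <- results[[1]]@skipped
  for (r in results[-1]) {
    same <- addMaps(same, r@sameCounts)
    diff <- addMaps(diff, r@diffCounts)
    skipped <- skipped + r@skipped
  }
  new("ComparisonResult", sameCounts = same, diffCounts = diff,
      totalSame = sum(same), totalDifferent = sum(diff),
      skipped = skipped, slot = results[[1]]@slot)
}

`%|0|%` <- function(x, default) {
  v <- unname(x)
  if (length(v) == 0 || is.na(v)) default else v
}

#' Two-proportion z-test
#'
#' Tests the null hypothesis that two population proportions are equal,
#' using the pooled-variance normal approximation:
#' `z = (p1 - p2) / sqrt(p (1 - p) (1/n1 + 1/n2))` with
#' `p = (x1 + x2) / (n1 + n2)`. A two-sided decision rule is applied at
#' the 0.05, 0.01 and 0.001 levels (critical values 1.95996, 2.57583,
#' 3.29053). The large-sample condition (pooled expected successes and
#' failures of at least 5 in each sample) is checked and a warning issued
#' when it fails.
#'
#' @param x1,n1,x2,n2 success and total counts.
#' @return a [ProportionTest-class].
#' @examples
#' twoProportionZTest(40, 100, 60, 100)
#' @export
twoProportionZTest <- function(x1, n1, x2, n2) {
  for (v in list(x1, n1, x2, n2)) assertScalarNumeric(v, "count")
  if (n1 <= 0 || n2 <= 0) stop("sample sizes must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2)
    stop("counts must satisfy 0 <= x <= n")
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (min(n1 * pp, n1 * (1 - pp), n2 * pp, n2 * (1 - pp)) < 5)
    warning("large-sample condition violated: pooled expected counts < 5")
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  alphas <- c(0.05, 0.01, 0.001)
  crit <- stats::qnorm(1 - alphas / 2)
  new("ProportionTest", x1 = x1, n1 = n1, x2 = x2, n2 = n2,
      pHat1 = p1, pHat2 = p2, pPooled = pp, z = z,
      significantAt = alphas[abs(z) > crit])
}

#' Normal-approximation confidence interval for a proportion
#'
#' `p +/- z * sqrt(p (1 - p) / n)`, truncated to \[0, 1\].
#'
#' @param x success count.
#' @param n total count (> 0).
#' @param level confidence level (default 0.95).
#' @return named numeric c(lower, upper).
#' @examples
#' proportionCI(50, 100)
#' @export
proportionCI <- function(x, n, level = 0.95) {
  if (n <= 0) stop("n must be positive")
  if (x < 0 || x > n) stop("x must satisfy 0 <= x <= n")
  p <- x / n
  zc <- stats::qnorm(1 - (1 - level) / 2)
  half <- zc * sqrt(p * (1 - p) / n)
  c(lower = max(0, p - half), upper = min(1, p + half))
}
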