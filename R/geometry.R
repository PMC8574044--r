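## Sequence-level guide-pair design rules.
##
## Coordinate conventions (used consistently everywhere):
##  * reference coordinates are 1-based inclusive on the top strand;
##  * promoter coordinates are signed relative to the transcription start
##    site, which is +1; there is no position 0;
##  * "distance" counts intervening bases plus one, i.e. adjacent bases are at
##    distance 1 and overlapping features at distance 0.

.asDNA <- function(sequence) {
  if (is(sequence, "DNAString")) sequence <- as.character(sequence)
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]+$", sequence))
    stop("sequence must contain only A, C, G, T (degenerate bases rejected)")
  Biostrings::DNAString(sequence)
}

#' Find all NGG PAM sites on both strands of a reference
#'
#' Every top-strand 3-nt window matching NGG is reported as a top-strand PAM;
#' every window reading NGG on the bottom strand (CCN on top) as a
#' bottom-strand PAM.  Coordinates are top-strand, 1-based.
#'
#' @param sequence DNA string (character or \code{DNAString}) over ACGT,
#'   length >= 3
#' @return a data.frame with columns \code{start}, \code{end}, \code{strand}
#'   ("top"/"bottom") and \code{pam} (the PAM read 5'->3' on its strand),
#'   ordered by start
#' @examples
#' findPams("AAGGA")   # one top-strand PAM at 2-4
#' findPams("CCTAA")   # one bottom-strand PAM at 1-3
#' @export
findPams <- function(sequence) {
  dna <- .asDNA(sequence)
  if (length(dna) < 3) stop("sequence must be at least 3 nt")
  top <- Biostrings::matchPattern("NGG", dna, fixed = FALSE)
  bot <- Biostrings::matchPattern("CCN", dna, fixed = FALSE)
  s <- as.character(dna)
  rc <- function(x) vapply(x, function(w) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(w))), character(1),
    USE.NAMES = FALSE)
  df <- rbind(
    if (length(top)) data.frame(
      start = BiocGenerics::start(top), end = BiocGenerics::end(top),
      strand = "top",
      pam = substring(s, BiocGenerics::start(top), BiocGenerics::end(top))),
    if (length(bot)) data.frame(
      start = BiocGenerics::start(bot), end = BiocGenerics::end(bot),
      strand = "bottom",
      pam = rc(substring(s, BiocGenerics::start(bot),
                         BiocGenerics::end(bot))))
  )
  if (is.null(df))
    df <- data.frame(start = integer(), end = integer(),
                     strand = character(), pam = character())
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build a guide site from a PAM position
#'
#' Extracts the 20-nt protospacer immediately 5' of the PAM on the targeted
#' strand.  For a top-strand PAM at positions p..p+2 the protospacer occupies
#' top positions p-20..p-1; for a bottom-strand PAM (CCN on top) it occupies
#' top positions p+3..p+22 and the spacer is the reverse complement of that
#' top-strand stretch.
#'
#' @param sequence the reference (character or \code{DNAString})
#' @param pamStart 1-based top-strand start of the 3-nt PAM
#' @param strand "top" or "bottom"
#' @return a \linkS4class{GuideSite}
#' @export
siteFromPam <- function(sequence, pamStart, strand = c("top", "bottom")) {
  strand <- match.arg(strand)
  dna <- .asDNA(sequence)
  L <- length(dna)
  pamStart <- as.integer(pamStart)
  if (pamStart < 1L || pamStart + 2L > L) stop("PAM window outside sequence")
  pam <- as.character(Biostrings::subseq(dna, pamStart, pamStart + 2L))
  if (strand == "top") {
    if (substr(pam, 2, 3) != "GG")
      stop("no top-strand NGG PAM at position ", pamStart)
    if (pamStart - 20L < 1L)
      stop("insufficient flanking sequence: need 20 nt 5' of the PAM")
    protoStart <- pamStart - 20L
    protoEnd <- pamStart - 1L
    spc <- as.character(Biostrings::subseq(dna, protoStart, protoEnd))
  } else {
    if (substr(pam, 1, 2) != "CC")
      stop("no bottom-strand NGG PAM at position ", pamStart)
    if (pamStart + 22L > L)
      stop("insufficient flanking sequence: need 20 nt 5' of the PAM")
    protoStart <- pamStart + 3L
    protoEnd <- pamStart + 22L
    spc <- as.character(Biostrings::reverseComplement(
      Biostrings::subseq(dna, protoStart, protoEnd)))
  }
  new("GuideSite", spacer = spc, strand = strand,
      protoStart = protoStart, protoEnd = protoEnd,
      pamStart = pamStart, pamEnd = pamStart + 2L)
}

#' Convert a signed promoter coordinate to a reference coordinate
#'
#' The TSS is +1; there is no position 0, so -1 is the base immediately
#' upstream of the TSS.
#'
#' @param pos signed promoter coordinate(s), nonzero
#' @param tssRef 1-based top-strand reference coordinate of the TSS
#' @return reference coordinate(s)
#' @export
promoterToRef <- function(pos, tssRef) {
  if (any(pos == 0)) stop("promoter coordinates have no position 0")
  ifelse(pos > 0, tssRef + pos - 1L, tssRef + pos)
}

#' Convert a reference coordinate to a signed promoter coordinate
#'
#' @param ref reference coordinate(s)
#' @param tssRef reference coordinate of the TSS (+1)
#' @return signed promoter coordinate(s), never 0
#' @export
refToPromoter <- function(ref, tssRef) {
  d <- ref - tssRef
  ifelse(d >= 0, d + 1L, d)
}

#' Distance from a guide site to the transcription start site
#'
#' The minimum, over protospacer bases, of the offset to the TSS; 0 when the
#' protospacer overlaps the TSS, 1 when immediately adjacent.
#'
#' @param site a \linkS4class{GuideSite}
#' @param tssRef reference coordinate of the TSS
#' @return distance in bp (>= 0)
#' @export
distanceToTss <- function(site, tssRef) {
  stopifnot(is(site, "GuideSite"))
  a <- site@protoStart
  b <- site@protoEnd
  if (tssRef >= a && tssRef <= b) return(0L)
  as.integer(min(abs(a - tssRef), abs(b - tssRef)))
}

.footprint <- function(site) {
  c(min(site@protoStart, site@pamStart), max(site@protoEnd, site@pamEnd))
}

#' Classify a repressor/derepressor guide pair
#'
#' Applies the steric-competition design rules.  dCas9 overhangs its target
#' by ~9 bp beyond the PAM-proximal edge but only ~1 bp beyond the PAM-distal
#' edge, so two non-overlapping sites compete for occupancy only when their
#' PAMs face each other across the gap (overhang sum 9 + 9 = 18 bp).  Pairs
#' with facing PAMs and a gap of at most 14 bp are classified "validated"
#' (experimentally confirmed spacing); facing pairs at 15-18 bp are
#' "marginal" (within the overhang arithmetic but untested); everything else
#' is "independent".
#'
#' The risk that the derepressing guide represses on its own:
#' \itemize{
#'   \item promoter context: "none" when the sgD protospacer lies wholly
#'     upstream of -60 (negligible repression), "partial" when its nearest
#'     base falls in -60..-28, "high" otherwise;
#'   \item elongation context: "none" when sgD base-pairs with the template
#'     strand (RNAP collides with the PAM-distal face and reads through),
#'     "high" when it base-pairs with the non-template strand.
#' }
#'
#' @param siteR,siteD \linkS4class{GuideSite}s for the repressing and
#'   derepressing guides on the same reference, non-overlapping
#' @param context "promoter" or "elongation"
#' @param tssRef reference coordinate of the TSS (required for promoter
#'   context)
#' @param promoterStrand strand on which the promoter reads 5'->3' ("top":
#'   transcription to the right of the TSS; "bottom": to the left)
#' @param templateStrand which reference strand is the template for the
#'   repressed transcript (required for elongation context)
#' @param gapConvention measure the gap between protospacer+PAM footprint
#'   edges (default) or between protospacer edges only
#' @return a \linkS4class{PairClassification}
#' @export
classifyPair <- function(siteR, siteD,
                         context = c("promoter", "elongation"),
                         tssRef = NA_integer_,
                         promoterStrand = c("top", "bottom"),
                         templateStrand = c("top", "bottom"),
                         gapConvention = c("footprint", "protospacer")) {
  context <- match.arg(context)
  promoterStrand <- match.arg(promoterStrand)
  gapConvention <- match.arg(gapConvention)
  stopifnot(is(siteR, "GuideSite"), is(siteD, "GuideSite"))

  fpR <- .footprint(siteR)
  fpD <- .footprint(siteD)
  if (fpR[1] <= fpD[2] && fpD[1] <= fpR[2])
    stop("protospacer+PAM regions overlap: overlapping targets are mutually ",
         "exclusive by sequence competition; use single-site repression ",
         "semantics instead")
  if (fpR[1] < fpD[1]) { left <- siteR; right <- siteD }
  else { left <- siteD; right <- siteR }

  gap <- if (gapConvention == "footprint")
    .footprint(right)[1] - .footprint(left)[2] - 1L
  else
    right@protoStart - left@protoEnd - 1L
  gap <- max(as.integer(gap), 0L)

  facing <- left@pamStart > left@protoEnd && right@pamEnd < right@protoStart
  overhangSum <- (if (left@pamStart > left@protoEnd) 9L else 1L) +
    (if (right@pamEnd < right@protoStart) 9L else 1L)

  verdict <- if (facing && overhangSum >= gap) {
    if (gap <= 14L) "validated" else "marginal"
  } else "independent"

  risk <- if (context == "promoter") {
    if (is.na(tssRef)) stop("promoter context requires tssRef")
    if (tssRef >= siteD@protoStart && tssRef <= siteD@protoEnd) "high"
    else {
      edge <- if (abs(siteD@protoStart - tssRef) < abs(siteD@protoEnd - tssRef))
        siteD@protoStart else siteD@protoEnd
      d <- edge - tssRef
      if (promoterStrand == "bottom") d <- -d  # orient: + downstream of TSS
      n <- if (d >= 0) d + 1L else d
      if (n <= -61) "none" else if (n <= -28 && n >= -60) "partial" else "high"
    }
  } else {
    templateStrand <- match.arg(templateStrand)
    targeted <- if (siteD@strand == "top") "bottom" else "top"
    if (targeted == templateStrand) "none" else "high"
  }

  new("PairClassification", gapBp = gap, pamsFacing = facing,
      competitive = verdict, sgdRepressionRisk = risk, context = context)
}

#' Remap a guide site onto the reverse complement of its reference
#'
#' Utility for strand-symmetry checks: the same physical site described on
#' the reverse-complemented reference has mirrored coordinates and the
#' opposite strand label, while the spacer sequence is unchanged.
#'
#' @param site a \linkS4class{GuideSite}
#' @param refLength length of the reference sequence
#' @return the remapped \linkS4class{GuideSite}
#' @export
revcompSite <- function(site, refLength) {
  stopifnot(is(site, "GuideSite"))
  flip <- function(a, b) c(refLength - b + 1L, refLength - a + 1L)
  pr <- flip(site@protoStart, site@protoEnd)
  pm <- flip(site@pamStart, site@pamEnd)
  new("GuideSite", spacer = site@spacer,
      strand = if (site@strand == "top") "bottom" else "top",
      protoStart = as.integer(pr[1]), protoEnd = as.integer(pr[2]),
      pamStart = as.integer(pm[1]), pamEnd = as.integer(pm[2]))
}
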