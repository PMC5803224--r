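#' Foraminifera-specific 18S rDNA primer set
#'
#' The semi-nested forward primer S15rF and reverse primer S19F used to
#' amplify the partial 18S rRNA gene of foraminifera, together with the
#' length of the sample tag appended 5' of the forward primer.  S15rF
#' contains no degenerate bases and is matched exactly during quality
#' filtering; S19F carries two R (A/G) ambiguities and is matched with IUPAC
#' expansion.
#'
#' @param forward forward primer sequence (5'-3').
#' @param reverse reverse primer sequence (5'-3'); its reverse complement is
#'   searched on the 3' end of reads.
#' @param tag_length length in nucleotides of the per-sample tag preceding
#'   the forward primer.
#' @return A list with elements `forward`, `reverse` and `tag_length`.
#' @export
#' @examples
#' foram_primers()
foram_primers <- function(forward = "GTGCATGGCCGTTCTTAGTTC",
                          reverse = "GTACRAGGCATTCCTRGTT",
                          tag_length = 8L) {
  stopifnot(nchar(forward) > 0, nchar(reverse) > 0)
  if (grepl("[^ACGTRYSWKMBDHVN]", forward) || forward != toupper(forward))
    stop("forward primer must be uppercase IUPAC DNA")
  if (grepl("[^ACGTRYSWKMBDHVN]", reverse) || reverse != toupper(reverse))
    stop("reverse primer must be uppercase IUPAC DNA")
  list(forward = forward, reverse = reverse, tag_length = as.integer(tag_length))
}
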