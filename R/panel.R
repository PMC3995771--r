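#' Published 18S rDNA candidate primer panel
#'
#' The panel of oligomers evaluated as broad-range eukaryotic 18S rDNA
#' primers: the degenerate oligomers designed by maximum-coverage search on
#' the SILVA SSU Ref NR eukaryotic alignment (ids like `391f`, `1132r`;
#' positions in *S. cerevisiae* 18S coordinates), the two manually modified
#' variants (`574*f`, `616*f`, which add degeneracy or drop a terminal
#' base to recover missed taxa), and commonly used literature primers.
#'
#' @param designed_only Return only the designed rows (drop literature
#'   primers).
#' @return Data frame: `primer_id`, `yeast_position`, `sequence`, `source`
#'   (`"designed"` or `"literature"`), `modified` (manually altered
#'   variant).
#' @export
candidate_primers <- function(designed_only = FALSE) {
  df <- data.frame(
    primer_id = c("391f", "550f", "563f", "574f", "574*f", "616f", "616*f",
                  "897f", "1132f", "1132r", "1182f", "1266f", "1423f",
                  "1423r", "1612r", "1626r",
                  "1380F", "1389F", "1510R", "1391F", "EukB", "Fwd1",
                  "Rev3", "fw", "rv"),
    yeast_position = c("391", "550", "563", "574", "574", "616", "616",
                       "897", "1132", "1150", "1182", "1266", "1423",
                       "1441", "1630", "1644",
                       "1625", "1634", "1787", "1770", "3'", "564",
                       "981", "366", "586"),
    sequence = c(
      "YGGAGARGGAGCHTGAGA", "GGRCMAGBCTGGTGCCAG", "GCCAGCAVCYGCGGTAAY",
      "CGGTAAYTCCAGCTCYAV", "CGGTAAYTCCAGCTCYV", "TTAAAAVGYTCGTAGTYG",
      "TTAAARVGYTCGTAGTYG", "AGAGGTGRAATTCTHRGA", "AYTTRAAGDAATTGACGG",
      "CCGTCAATTHCTTYAART", "AATTYGACTCAACDCRGG", "RGTGGTGCATGGCCGYTB",
      "AACAGGTCHGWRATGCCC", "GGGCATYWCDGACCTGTT", "ACAAAKGGCAGGGACDYA",
      "GACRGGMGGTGTGBACAA",
      "CCCTGCCHTTTGTACACAC", "TTGTACACACCGCCC", "CCTTCYGCAGGTTCACCTAC",
      "GTACACACCGCCCGTC", "TGATCCTTCTGCAGGTTCACCTAC",
      "CCAGCASCYGCGGTAATTCC", "ACTTTCGTTCTTGATYRA",
      "ATTAGGGTTCGATTCCGGAGAGG", "CTGGAATTACCGCGGSTGCTG"),
    source = c(rep("designed", 16L), rep("literature", 9L)),
    modified = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE,
                 rep(FALSE, 9L), rep(FALSE, 9L)),
    stringsAsFactors = FALSE)
  if (designed_only) df[df$source == "designed", ] else df
}
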