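# Reference karyotype: the per-chromosome template used both to size phantom
# chromosomes and as the target of identification.

.CHROM_LEVELS <- c(as.character(1:22), "X", "Y")

# Classical cytogenetic grouping of the human karyotype, with the sex
# chromosomes collected into an extra group H.
.GROUP_RULE <- c(
  rep("A", 3), rep("B", 2), rep("C", 7), rep("D", 3),
  rep("E", 3), rep("F", 2), rep("G", 2), "H", "H"
)
names(.GROUP_RULE) <- .CHROM_LEVELS

.ACROCENTRIC <- c("13", "14", "15", "21", "22", "Y")

#' Load the reference karyotype table
#'
#' Reads and validates the per-chromosome template: DNA content in Mbp,
#' protein-coding gene density (genes per Mbp), canonical centromere index
#' (short-arm length as a percentage of total length) and cytogenetic group
#' A--H. The packaged default covers the 24 human chromosome types with sizes
#' from the reference genome assembly (chromosome 1, 248.9 Mbp, the largest;
#' chromosome 21, 46.7 Mbp, the smallest).
#'
#' @param path Optional path to a CSV with columns
#'   `chrom_id,mbp,gene_density,canonical_ci,group`. When `NULL` the packaged
#'   default table is used.
#' @return A `data.frame` of class `reference_karyotype` with one row per
#'   chromosome type, ordered 1..22, X, Y.
#' @examples
#' ref <- load_reference()
#' ref[ref$chrom_id == "1", "mbp"]   # 248.9
#' @export
load_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_karyotype.csv",
                        package = "karyo3d", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("reference karyotype file not found: ", path)
  ref <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom_id = "character"))
  validate_reference(ref)
  ref <- ref[match(.CHROM_LEVELS, ref$chrom_id), , drop = FALSE]
  rownames(ref) <- NULL
  class(ref) <- c("reference_karyotype", "data.frame")
  ref
}

validate_reference <- function(ref) {
  required <- c("chrom_id", "mbp", "gene_density", "canonical_ci", "group")
  missing_cols <- setdiff(required, names(ref))
  if (length(missing_cols)) {
    stop("reference karyotype is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dup <- ref$chrom_id[duplicated(ref$chrom_id)]
  if (length(dup)) {
    stop("duplicate chromosome row(s) in reference karyotype: ",
         paste(unique(dup), collapse = ", "))
  }
  absent <- setdiff(.CHROM_LEVELS, ref$chrom_id)
  if (length(absent)) {
    stop("reference karyotype is missing chromosome(s): ",
         paste(absent, collapse = ", "))
  }
  unknown <- setdiff(ref$chrom_id, .CHROM_LEVELS)
  if (length(unknown)) {
    stop("unknown chromosome row(s) in reference karyotype: ",
         paste(unknown, collapse = ", "))
  }
  if (nrow(ref) != 24L) stop("reference karyotype must have exactly 24 rows")
  for (col in c("mbp", "gene_density", "canonical_ci")) {
    bad <- ref$chrom_id[!is.finite(ref[[col]]) | ref[[col]] <= 0]
    if (length(bad)) {
      stop("non-positive or missing ", col, " for chromosome(s): ",
           paste(bad, collapse = ", "))
    }
  }
  if (any(ref$canonical_ci > 50)) {
    bad <- ref$chrom_id[ref$canonical_ci > 50]
    stop("canonical_ci must lie in (0, 50]; offending chromosome(s): ",
         paste(bad, collapse = ", "))
  }
  acro_ci <- ref$canonical_ci[match(.ACROCENTRIC, ref$chrom_id)]
  if (any(acro_ci >= 20)) {
    stop("acrocentric chromosomes (",
         paste(.ACROCENTRIC, collapse = ","),
         ") must have canonical_ci < 20")
  }
  if (ref$chrom_id[which.max(ref$mbp)] != "1") {
    stop("chromosome 1 must carry the largest mbp value")
  }
  if (ref$chrom_id[which.min(ref$mbp)] != "21") {
    stop("chromosome 21 must carry the smallest mbp value")
  }
  expected_group <- unname(.GROUP_RULE[ref$chrom_id])
  mismatch <- ref$chrom_id[ref$group != expected_group]
  if (length(mismatch)) {
    stop("group label disagrees with the cytogenetic grouping for: ",
         paste(mismatch, collapse = ", "))
  }
  invisible(TRUE)
}

#' Cytogenetic group of a chromosome
#'
#' Deterministic lookup of the classical group label: 1--3 A, 4--5 B,
#' 6--12 C, 13--15 D, 16--18 E, 19--20 F, 21--22 G, and X/Y in H.
#'
#' @param chrom_id Character vector of chromosome names in `1..22, X, Y`.
#' @return Character vector of group labels.
#' @examples
#' group_of(c("2", "14", "X"))  # "A" "D" "H"
#' @export
group_of <- function(chrom_id) {
  chrom_id <- as.character(chrom_id)
  unknown <- setdiff(chrom_id, .CHROM_LEVELS)
  if (length(unknown)) {
    stop("unknown chromosome name(s): ", paste(unique(unknown), collapse = ", "))
  }
  unname(.GROUP_RULE[chrom_id])
}

#' Expand a karyotype template into its 46 chromosome slots
#'
#' @param sex `"XY"` (default, one X and one Y) or `"XX"`.
#' @return Character vector of 46 chromosome names (each autosome twice).
#' @export
karyotype_slots <- function(sex = c("XY", "XX")) {
  sex <- match.arg(sex)
  autos <- rep(as.character(1:22), each = 2L)
  c(autos, if (sex == "XY") c("X", "Y") else c("X", "X"))
}

#' @export
print.reference_karyotype <- function(x, ...) {
  cat("Reference karyotype: 24 chromosome types,",
      sprintf("diploid male genome %.0f Mbp\n",
              2 * sum(x$mbp[x$chrom_id %in% as.character(1:22)]) +
                x$mbp[x$chrom_id == "X"] + x$mbp[x$chrom_id == "Y"]))
  print.data.frame(x, ...)
  invisible(x)
}
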