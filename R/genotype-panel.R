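#' Default serial allopolyploid genotype panel
#'
#' Returns the six-genotype panel used throughout the package: the two diploid
#' parents (`AA`, `CC`), the F1 hybrid (`AC`), the two reciprocal triploids
#' (`AAC`, `CCA`) and the allotetraploid (`CCAA`), together with the number of
#' copies of each subgenome they carry.
#'
#' Each genotype's *relative dosage* of a subgenome is its copy number divided
#' by the total genome-copy complement; over the A-carrying genotypes
#' (`AA`, `AAC`, `AC`, `CCAA`, `CCA`) the A dosage runs
#' 1, 2/3, 1/2, 1/2, 1/3 — the dosage series that downstream correlation
#' analysis uses. The C series is symmetric.
#'
#' @return A tibble of class `genotype_panel` with columns `genotype`,
#'   `copies_a` and `copies_c`.
#' @examples
#' build_genotype_panel()
#' @seealso [relative_dosage()], [dosage_vector()]
#' @export
build_genotype_panel <- function() {
  genotype_panel(tibble::tibble(
    genotype = c("AA", "CC", "AC", "AAC", "CCA", "CCAA"),
    copies_a = c(2L, 0L, 1L, 2L, 1L, 2L),
    copies_c = c(0L, 2L, 1L, 1L, 2L, 2L)
  ))
}

#' Construct and validate a genotype panel
#'
#' @param entries Data frame with columns `genotype` (unique names),
#'   `copies_a` and `copies_c` (non-negative integers, at least one copy in
#'   total per genotype).
#' @return A validated `genotype_panel` tibble.
#' @export
genotype_panel <- function(entries) {
  entries <- tibble::as_tibble(entries)
  required <- c("genotype", "copies_a", "copies_c")
  missing <- setdiff(required, names(entries))
  if (length(missing) > 0) {
    rlang::abort(paste0("genotype panel is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(entries$genotype)) {
    rlang::abort("genotype names must be unique")
  }
  if (any(entries$copies_a < 0) || any(entries$copies_c < 0)) {
    rlang::abort("subgenome copy numbers must be non-negative")
  }
  if (any(entries$copies_a + entries$copies_c < 1)) {
    rlang::abort("every genotype must carry at least one genome copy")
  }
  entries$copies_a <- as.integer(entries$copies_a)
  entries$copies_c <- as.integer(entries$copies_c)
  class(entries) <- c("genotype_panel", class(entries))
  entries
}

#' Relative subgenome dosage of a genotype
#'
#' The relative dosage of subgenome `subgenome` in genotype `genotype` is
#' `copies / (copies_a + copies_c)`, e.g. 2/3 for A in the AAC triploid and
#' 1/2 for A in both AC and CCAA (which is why those two genotypes are
#' expression-equivalent for dosage-tracking genes despite different absolute
#' copy numbers).
#'
#' @param panel A `genotype_panel`.
#' @param genotype Character vector of genotype names (recycled against
#'   `subgenome`).
#' @param subgenome `"A"` or `"C"`, same length as `genotype` or length 1.
#' @return Numeric vector of dosages in `[0, 1]`.
#' @examples
#' panel <- build_genotype_panel()
#' relative_dosage(panel, "AAC", "A") # 2/3
#' relative_dosage(panel, "CCAA", "A") # 1/2
#' @export
relative_dosage <- function(panel, genotype, subgenome) {
  stopifnot(inherits(panel, "genotype_panel"))
  bad <- setdiff(unique(genotype), panel$genotype)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown genotype(s): ", paste(bad, collapse = ", ")))
  }
  if (!all(subgenome %in% c("A", "C"))) {
    rlang::abort("subgenome must be \"A\" or \"C\"")
  }
  n <- max(length(genotype), length(subgenome))
  genotype <- rep_len(genotype, n)
  subgenome <- rep_len(subgenome, n)
  idx <- match(genotype, panel$genotype)
  copies <- ifelse(subgenome == "A", panel$copies_a[idx], panel$copies_c[idx])
  total <- panel$copies_a[idx] + panel$copies_c[idx]
  copies / total
}

#' Dosage series of the genotypes carrying a subgenome
#'
#' Returns, for one subgenome, the genotypes that carry it (dosage > 0) and
#' their relative dosages, in panel order. These are the points entering the
#' per-gene dosage correlation; the non-carrier parent is excluded.
#'
#' @inheritParams relative_dosage
#' @param subgenome `"A"` or `"C"`.
#' @return A tibble with columns `genotype` and `dosage`.
#' @examples
#' dosage_vector(build_genotype_panel(), "A")
#' @export
dosage_vector <- function(panel, subgenome) {
  stopifnot(inherits(panel, "genotype_panel"), length(subgenome) == 1)
  d <- relative_dosage(panel, panel$genotype, subgenome)
  tibble::tibble(genotype = panel$genotype, dosage = d)[d > 0, ]
}

#' Genotypes carrying both subgenomes
#'
#' @inheritParams relative_dosage
#' @return Character vector of hybrid/polyploid genotype names (both
#'   subgenomes present), in panel order.
#' @export
hybrid_genotypes <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  panel$genotype[panel$copies_a > 0 & panel$copies_c > 0]
}

#' Single-subgenome (parental) genotype for a subgenome
#'
#' @inheritParams dosage_vector
#' @return The genotype name carrying only the requested subgenome.
#' @keywords internal
parent_genotype <- function(panel, subgenome) {
  stopifnot(length(subgenome) == 1, subgenome %in% c("A", "C"))
  sel <- if (subgenome == "A") {
    panel$copies_a > 0 & panel$copies_c == 0
  } else {
    panel$copies_c > 0 & panel$copies_a == 0
  }
  g <- panel$genotype[sel]
  if (length(g) != 1) {
    rlang::abort(paste0("panel must contain exactly one pure ", subgenome,
                        " parent; found ", length(g)))
  }
  g
}
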