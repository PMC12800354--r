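# Readers/writers for the standard plain-text formats the pipeline uses:
# GMT gene sets, genes x samples expression TSV, clinical/survival CSV and
# (optionally, via the png package) slide/mask rasters.

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line; tab-separated set name, description, then
#' member gene ids.
#'
#' @param path file path.
#' @return named list of gene-id character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 50))
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}

#' Write a GMT gene-set file
#' @param sets named list of gene-id vectors.
#' @param path output path.
#' @param description description field per set (recycled).
#' @export
writeGMT <- function(sets, path, description = "synthetic signature") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Read a genes x samples expression TSV
#'
#' Tab-separated, header row of sample ids, first column of gene ids.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
readExpression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  as.matrix(df)
}

#' Write a genes x samples expression TSV
#' @param expr matrix with dimnames.
#' @param path output path.
#' @export
writeExpression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a synthetic cohort to a directory
#'
#' Writes slides and tumour masks as PNG (requires the `png` package),
#' expression as TSV, signatures as GMT, and the clinical and survival
#' tables as CSV.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if missing).
#' @param writeImages write slide/mask PNGs (default TRUE).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir, writeImages = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (writeImages) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the 'png' package is required to write slide images")
    sdir <- file.path(dir, "slides"); mdir <- file.path(dir, "masks")
    dir.create(sdir, showWarnings = FALSE); dir.create(mdir, showWarnings = FALSE)
    for (s in cohort@slides) {
      png::writePNG(s@image / 255, file.path(sdir, paste0(s@slideId, ".png")))
      if (!is.null(s@tumourMask))
        png::writePNG(s@tumourMask, file.path(mdir, paste0(s@slideId, ".png")))
    }
  }
  writeExpression(cohort@expression, file.path(dir, "expression.tsv"))
  writeGMT(cohort@signatures, file.path(dir, "signatures.gmt"))
  utils::write.csv(cohort@clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort@survival, file.path(dir, "survival.csv"),
                   row.names = FALSE)
  slideTab <- do.call(rbind, lapply(cohort@slides, function(s)
    data.frame(slide_id = s@slideId, patient_id = s@patientId,
               sample_type = s@sampleType, rna_linked = s@rnaLinked,
               true_class = s@trueClass)))
  utils::write.csv(slideTab, file.path(dir, "slides.csv"), row.names = FALSE)
  invisible(dir)
}
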