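## File dialects: clinical/fusion/mutation/expression/methylation tables are
## plain TSV; segments use the SEG convention (1-based inclusive on disk,
## converted to 0-based half-open in memory); gene and region annotations are
## BED-style (0-based half-open on disk, kept as-is); pathways are GMT.

.NONSILENT <- c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
                "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del",
                "In_Frame_Ins", "Splice_Site", "Translation_Start_Site")

.emptyClinical <- function() {
  data.frame(sample_id = character(), group = character(),
             ancestry = character(), age = numeric(), psa = numeric(),
             gleason = character(), stage = character(),
             bcr_event = character(), bcr_time = numeric(),
             stringsAsFactors = FALSE)
}
.emptyFusions <- function() {
  data.frame(sample_id = character(), gene_5p = character(),
             gene_3p = character(), source = character(),
             stringsAsFactors = FALSE)
}
.emptyMutations <- function() {
  data.frame(sample_id = character(), gene = character(),
             variant_class = character(), stringsAsFactors = FALSE)
}
.emptySegments <- function() {
  data.frame(sample_id = character(), chrom = character(),
             start = numeric(), end = numeric(), value = numeric(),
             stringsAsFactors = FALSE)
}
.emptyProbeAnno <- function() {
  data.frame(probe = character(), chrom = character(), gene = character(),
             region_class = character(), stringsAsFactors = FALSE)
}

#' Construct an ErgCohort
#'
#' Assembles the cohort container from in-memory tables; every layer except
#' the clinical table may be empty. Validity (unique sample IDs, omics
#' samples resolving to clinical records, betas in [0,1], non-overlapping
#' segments) is enforced on construction.
#'
#' @param clinical per-sample data.frame; missing optional columns are
#'   filled with NA/UNKNOWN.
#' @param fusions,mutations,segments,probe_anno layer data.frames.
#' @param expression,methylation feature x sample matrices.
#' @param genes,regions `GRanges` annotations (may be empty).
#' @param genome named numeric chromosome lengths.
#' @param thresholds list from [ergThresholds()].
#' @return A validated [ErgCohort-class] object.
#' @export
ErgCohort <- function(clinical,
                      fusions = .emptyFusions(),
                      mutations = .emptyMutations(),
                      segments = .emptySegments(),
                      expression = matrix(numeric(), 0, 0),
                      methylation = matrix(numeric(), 0, 0),
                      probe_anno = .emptyProbeAnno(),
                      genes = GRanges(),
                      regions = GRanges(),
                      genome = numeric(),
                      thresholds = ergThresholds()) {
  defaults <- list(group = "UNASSIGNED", ancestry = "UNKNOWN",
                   age = NA_real_, psa = NA_real_, gleason = "UNKNOWN",
                   stage = "UNKNOWN", bcr_event = "unknown",
                   bcr_time = NA_real_)
  for (nm in names(defaults))
    if (is.null(clinical[[nm]])) clinical[[nm]] <- defaults[[nm]]
  clinical$sample_id <- as.character(clinical$sample_id)
  new("ErgCohort", clinical = clinical, fusions = fusions,
      mutations = mutations, segments = segments,
      expression = expression, methylation = methylation,
      probeAnno = probe_anno, genes = genes, regions = regions,
      genome = genome, thresholds = thresholds)
}

.readTsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  df
}

.checkCoords <- function(start, end, path) {
  bad <- which(!is.finite(start) | !is.finite(end) | end <= start |
                 start < 0)
  if (length(bad))
    stop("malformed coordinates in ", path, " at data line ", bad[1L])
}

#' Read a SEG-style segment file
#'
#' On disk: sample, chrom, start, end, value with 1-based inclusive
#' coordinates (the SEG convention); in memory coordinates are 0-based
#' half-open.
#'
#' @param path TSV file with columns sample_id, chrom, start, end, value.
#' @return segment data.frame in internal coordinates.
#' @export
readSeg <- function(path) {
  df <- .readTsv(path, c("sample_id", "chrom", "start", "end", "value"))
  if (!nrow(df)) return(.emptySegments())
  out <- data.frame(sample_id = as.character(df$sample_id),
                    chrom = as.character(df$chrom),
                    start = as.numeric(df$start) - 1,
                    end = as.numeric(df$end),
                    value = as.numeric(df$value),
                    stringsAsFactors = FALSE)
  .checkCoords(out$start, out$end, path)
  out
}

.writeSeg <- function(seg, path) {
  out <- seg
  out$start <- out$start + 1
  utils::write.table(out[c("sample_id", "chrom", "start", "end", "value")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a BED-style annotation of genes or regions
#'
#' 0-based half-open, columns chrom/start/end/name plus one attribute
#' column (`role` for genes, `level` for regions).
#'
#' @param path BED-style TSV.
#' @param attribute name of the 5th column.
#' @return `GRanges` with mcols `symbol`/`name` and the attribute.
#' @export
readBed <- function(path, attribute = c("role", "level")) {
  attribute <- match.arg(attribute)
  df <- .readTsv(path, c("chrom", "start", "end", "name", attribute))
  .checkCoords(as.numeric(df$start), as.numeric(df$end), path)
  gr <- GRanges(df$chrom,
                IRanges(start = as.numeric(df$start) + 1,
                        end = as.numeric(df$end)))
  if (attribute == "role") {
    S4Vectors::mcols(gr)$symbol <- as.character(df$name)
    S4Vectors::mcols(gr)$role <- as.character(df$role)
  } else {
    S4Vectors::mcols(gr)$name <- as.character(df$name)
    S4Vectors::mcols(gr)$level <- as.character(df$level)
  }
  gr
}

.writeBed <- function(gr, path, attribute) {
  mc <- S4Vectors::mcols(gr)
  nm <- if (attribute == "role") mc$symbol else mc$name
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   name = nm, stringsAsFactors = FALSE)
  df[[attribute]] <- as.character(mc[[attribute]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.readMatrix <- function(path, feature_col) {
  df <- .readTsv(path, feature_col)
  m <- as.matrix(df[setdiff(names(df), feature_col)])
  rownames(m) <- df[[feature_col]]
  storage.mode(m) <- "double"
  m
}

.writeMatrix <- function(m, path, feature_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- feature_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a GMT pathway file
#'
#' @param path GMT file: name, description, member genes, tab-separated.
#' @return named list of character vectors of member genes.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line in ", path)
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1L))
  if (any(lengths(out) == 0L)) stop("empty pathway in ", path)
  out
}

#' Read a full cohort directory
#'
#' Expects the fixed file layout written by [writeCohortDir()]:
#' `clinical.tsv` (required), and optionally `fusions.tsv`,
#' `mutations.tsv` (MAF-minimal: Hugo_Symbol, Tumor_Sample_Barcode,
#' Variant_Classification), `segments.seg`, `genes.bed`, `regions.bed`,
#' `genome.tsv`, `expression.tsv`, `methylation.tsv`, `probes.tsv`.
#' Mutation records are mapped to nonsilent/silent from the MAF
#' Variant_Classification vocabulary. Cross-reference failures (an omics
#' sample absent from the clinical table, betas outside [0,1]) surface as
#' validation errors naming the offending IDs.
#'
#' @param dir directory path.
#' @param thresholds list from [ergThresholds()].
#' @return An [ErgCohort-class].
#' @export
readCohortDir <- function(dir, thresholds = ergThresholds()) {
  p <- function(f) file.path(dir, f)
  cl <- .readTsv(p("clinical.tsv"), c("sample_id"))
  fus <- if (file.exists(p("fusions.tsv")))
    .readTsv(p("fusions.tsv"), c("sample_id", "gene_5p", "gene_3p", "source"))
  else .emptyFusions()
  if (nrow(fus) && any(fus$gene_5p == fus$gene_3p))
    stop("fusion with identical 5' and 3' partner in ", p("fusions.tsv"))
  mut <- if (file.exists(p("mutations.tsv"))) {
    maf <- .readTsv(p("mutations.tsv"),
                    c("Hugo_Symbol", "Tumor_Sample_Barcode",
                      "Variant_Classification"))
    data.frame(sample_id = as.character(maf$Tumor_Sample_Barcode),
               gene = as.character(maf$Hugo_Symbol),
               variant_class = ifelse(maf$Variant_Classification %in%
                                        .NONSILENT, "nonsilent", "silent"),
               stringsAsFactors = FALSE)
  } else .emptyMutations()
  seg <- if (file.exists(p("segments.seg"))) readSeg(p("segments.seg"))
  else .emptySegments()
  genes <- if (file.exists(p("genes.bed"))) readBed(p("genes.bed"), "role")
  else GRanges()
  regions <- if (file.exists(p("regions.bed"))) readBed(p("regions.bed"), "level")
  else GRanges()
  genome <- if (file.exists(p("genome.tsv"))) {
    g <- .readTsv(p("genome.tsv"), c("chrom", "length"))
    stats::setNames(as.numeric(g$length), g$chrom)
  } else numeric()
  expr <- if (file.exists(p("expression.tsv")))
    .readMatrix(p("expression.tsv"), "gene") else matrix(numeric(), 0, 0)
  meth <- if (file.exists(p("methylation.tsv")))
    .readMatrix(p("methylation.tsv"), "probe") else matrix(numeric(), 0, 0)
  panno <- if (file.exists(p("probes.tsv")))
    .readTsv(p("probes.tsv"), c("probe", "chrom", "gene", "region_class"))
  else .emptyProbeAnno()
  ErgCohort(clinical = cl, fusions = fus, mutations = mut, segments = seg,
            expression = expr, methylation = meth, probe_anno = panno,
            genes = genes, regions = regions, genome = genome,
            thresholds = thresholds)
}

#' Write a cohort to a directory
#'
#' Inverse of [readCohortDir()]; empty layers are skipped. Writing then
#' reading returns an equal cohort (coordinate conversions round-trip).
#'
#' @param cohort an `ErgCohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohortDir <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  w <- function(df, f) utils::write.table(df, p(f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  w(clinical(cohort), "clinical.tsv")
  if (nrow(fusionCalls(cohort))) w(fusionCalls(cohort), "fusions.tsv")
  mut <- mutationCalls(cohort)
  if (nrow(mut)) {
    maf <- data.frame(Hugo_Symbol = mut$gene,
                      Tumor_Sample_Barcode = mut$sample_id,
                      Variant_Classification = ifelse(
                        mut$variant_class == "nonsilent",
                        "Missense_Mutation", "Silent"),
                      stringsAsFactors = FALSE)
    w(maf, "mutations.tsv")
  }
  if (nrow(segTable(cohort))) .writeSeg(segTable(cohort), p("segments.seg"))
  if (length(geneAnno(cohort))) .writeBed(geneAnno(cohort), p("genes.bed"), "role")
  if (length(regionAnno(cohort))) .writeBed(regionAnno(cohort), p("regions.bed"), "level")
  if (length(cohortGenome(cohort)))
    w(data.frame(chrom = names(cohortGenome(cohort)),
                 length = unname(cohortGenome(cohort))), "genome.tsv")
  if (ncol(exprCounts(cohort)))
    .writeMatrix(exprCounts(cohort), p("expression.tsv"), "gene")
  if (ncol(methBeta(cohort)))
    .writeMatrix(methBeta(cohort), p("methylation.tsv"), "probe")
  if (nrow(probeAnno(cohort))) w(probeAnno(cohort), "probes.tsv")
  invisible(dir)
}

#' Write / read a group-comparison result table
#'
#' Deterministic column order `item, freq_pos, freq_neg, delta, test_used,
#' p, significant` (extra columns appended alphabetically); an empty
#' result yields a header-only file. `readComparison(writeComparison(x))`
#' returns an equal table.
#'
#' @param comparison data.frame as returned by the `compare*` functions.
#' @param path output TSV path.
#' @return `path` invisibly (write); the data.frame (read).
#' @export
writeComparison <- function(comparison, path) {
  lead <- intersect(c("item", "freq_pos", "freq_neg", "delta", "test_used",
                      "p", "significant"), names(comparison))
  rest <- sort(setdiff(names(comparison), lead))
  utils::write.table(comparison[c(lead, rest)], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeComparison
#' @export
readComparison <- function(path) {
  df <- .readTsv(path)
  if ("significant" %in% names(df))
    df$significant <- as.logical(df$significant)
  df
}
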