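#' Repeat-element class vocabulary
#'
#' Classes recognised by [read_repeat_table()] and used throughout repeat
#' summaries. Class strings from RepeatMasker-style tables are mapped onto
#' this vocabulary by prefix; anything unrecognised falls into `"other"`.
#'
#' @return Character vector of class names.
#' @export
re_classes <- function() {
  c("SINE", "LINE1", "LINE_other", "LTR", "DNA",
    "simple_repeat", "low_complexity", "satellite", "other")
}

#' Map raw repeat class/family strings onto the declared vocabulary
#'
#' `"SINE/tRNA"` maps to `SINE`, `"LINE/L1"` (and `"LINE1"`) to `LINE1`,
#' other LINE families to `LINE_other`, and unknown strings to `other`.
#'
#' @param x character vector of raw class strings (e.g. `"SINE/tRNA"`).
#' @return factor with levels [re_classes()].
#' @export
map_re_class <- function(x) {
  x <- as.character(x)
  out <- rep("other", length(x))
  out[grepl("^SINE", x, ignore.case = TRUE)] <- "SINE"
  is_line <- grepl("^LINE", x, ignore.case = TRUE)
  out[is_line] <- "LINE_other"
  out[is_line & grepl("^LINE[-_/]?(1|L1)|^LINE/L1", x, ignore.case = TRUE)] <- "LINE1"
  out[grepl("^LTR", x, ignore.case = TRUE)] <- "LTR"
  out[grepl("^DNA", x, ignore.case = TRUE)] <- "DNA"
  out[grepl("^Simple[-_ ]?repeat", x, ignore.case = TRUE)] <- "simple_repeat"
  out[grepl("^Low[-_ ]?complexity", x, ignore.case = TRUE)] <- "low_complexity"
  out[grepl("^Satellite", x, ignore.case = TRUE)] <- "satellite"
  factor(out, levels = re_classes())
}

new_genome_annotation <- function(genes, transcripts, exons) {
  stopifnot(is(genes, "GRanges"), is(transcripts, "GRanges"), is(exons, "GRanges"))
  obj <- structure(list(genes = genes, transcripts = transcripts, exons = exons),
                   class = "genome_annotation")
  validate_annotation(obj)
  obj
}

validate_annotation <- function(ann) {
  ex <- ann$exons
  tx <- ann$transcripts
  if (length(ex)) {
    if (is.null(ex$transcript_id) || anyNA(ex$transcript_id) ||
        any(!nzchar(ex$transcript_id)))
      stop("structural error: exon without a parent transcript")
    m <- match(ex$transcript_id, tx$transcript_id)
    if (anyNA(m))
      stop("structural error: exon parent transcript not found: ",
           paste(unique(ex$transcript_id[is.na(m)]), collapse = ", "))
    bad <- start(ex) < start(tx)[m] | end(ex) > end(tx)[m] |
      as.character(seqnames(ex)) != as.character(seqnames(tx))[m]
    if (any(bad))
      stop("structural error: exon outside its transcript span")
  }
  invisible(ann)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$genes), "genes,",
      length(x$transcripts), "transcripts,", length(x$exons), "exons\n")
  bt <- table(x$genes$biotype)
  if (length(bt)) cat("  biotypes:",
                      paste(names(bt), bt, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

.first_chr <- function(x) {
  # GFF3 attributes may come back as CharacterList
  if (is(x, "List") || is.list(x))
    vapply(x, function(v) if (length(v)) as.character(v[[1]]) else NA_character_,
           character(1))
  else as.character(x)
}

#' Read a GFF3/GTF genome annotation
#'
#' Parses gene, transcript (or mRNA) and exon records into a
#' `genome_annotation` object: three `GRanges` (genes with `gene_id` and
#' `biotype`, transcripts with `transcript_id` and `gene_id`, exons with
#' `transcript_id` and `gene_id`). The file's 1-based inclusive coordinates
#' are kept in the Bioconductor 1-based closed convention used throughout
#' the package.
#'
#' @param path path to a GFF3 or GTF file.
#' @return a `genome_annotation` object.
#' @export
read_annotation <- function(path) {
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) stop("annotation parse error in '", path,
                                          "': ", conditionMessage(e)))
  if (any(width(gr) < 1L)) stop("annotation parse error: record with end < start")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  txs <- gr[type %in% c("transcript", "mRNA")]
  exons <- gr[type == "exon"]
  if (length(genes) == 0L || length(exons) == 0L)
    stop("annotation parse error: gene/exon features missing")

  get_attr <- function(g, nm) {
    if (nm %in% names(mcols(g))) .first_chr(mcols(g)[[nm]]) else rep(NA_character_, length(g))
  }
  gid <- get_attr(genes, "gene_id")
  if (all(is.na(gid))) gid <- get_attr(genes, "ID")
  biotype <- get_attr(genes, "gene_biotype")
  if (all(is.na(biotype))) biotype <- get_attr(genes, "biotype")
  mcols(genes) <- S4Vectors::DataFrame(gene_id = gid, biotype = biotype)

  tid <- get_attr(txs, "transcript_id")
  if (all(is.na(tid))) tid <- get_attr(txs, "ID")
  tgid <- get_attr(txs, "gene_id")
  if (all(is.na(tgid))) tgid <- get_attr(txs, "Parent")
  mcols(txs) <- S4Vectors::DataFrame(transcript_id = tid, gene_id = tgid)

  etid <- get_attr(exons, "transcript_id")
  if (all(is.na(etid))) etid <- get_attr(exons, "Parent")
  if (anyNA(etid)) stop("structural error: exon without a parent transcript")
  egid <- get_attr(exons, "gene_id")
  if (all(is.na(egid))) egid <- txs$gene_id[match(etid, txs$transcript_id)]
  mcols(exons) <- S4Vectors::DataFrame(transcript_id = etid, gene_id = egid)

  new_genome_annotation(sort(genes), sort(txs), sort(exons))
}

#' Write a genome annotation as GFF3
#'
#' Inverse of [read_annotation()]: round-tripping through a file reproduces
#' the same records.
#'
#' @param ann a `genome_annotation`.
#' @param path output path.
#' @export
write_annotation <- function(ann, path) {
  g <- ann$genes; t <- ann$transcripts; e <- ann$exons
  mcols(g) <- S4Vectors::DataFrame(type = "gene", ID = g$gene_id,
                                   gene_id = g$gene_id, biotype = g$biotype)
  mcols(t) <- S4Vectors::DataFrame(type = "transcript", ID = t$transcript_id,
                                   Parent = t$gene_id,
                                   transcript_id = t$transcript_id,
                                   gene_id = t$gene_id)
  mcols(e) <- S4Vectors::DataFrame(type = "exon", Parent = e$transcript_id,
                                   transcript_id = e$transcript_id,
                                   gene_id = e$gene_id)
  rtracklayer::export(c(g, t, e), path, format = "gff3")
  invisible(path)
}

#' Construct a per-sample read interval set
#'
#' @param reads `GRanges` of read alignment intervals.
#' @param sample_id sample identifier.
#' @param total_mapped total mapped read count used as the depth denominator
#'   in RPKM/CPM; defaults to `length(reads)`. The records may be a filtered
#'   subset of this denominator.
#' @return a `read_set` object.
#' @export
read_set <- function(reads, sample_id, total_mapped = length(reads)) {
  stopifnot(is(reads, "GRanges"))
  if (any(width(reads) < 1L)) stop("read intervals must have positive length")
  if (total_mapped < 0) stop("total_mapped must be non-negative")
  structure(list(sample_id = as.character(sample_id), reads = reads,
                 total_mapped = as.numeric(total_mapped)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set '", x$sample_id, "': ", length(x$reads), " records, ",
      "total mapped ", format(x$total_mapped, big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Read a BED file of read alignment intervals
#'
#' BED is 0-based half-open; coordinates are converted to the 1-based closed
#' `GRanges` convention. Read length in nt is taken as the interval length.
#'
#' @inheritParams read_set
#' @param path path to a BED file (may be empty).
#' @param total_mapped optional depth denominator; defaults to the record
#'   count.
#' @return a `read_set`.
#' @export
read_alignments <- function(path, sample_id, total_mapped = NULL) {
  if (file.size(path) %in% c(0L, NA)) {
    gr <- GRanges()
  } else {
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e) stop("BED parse error in '", path, "': ",
                                            conditionMessage(e)))
  }
  if (length(gr) && any(start(gr) < 1L))
    stop("BED parse error: negative coordinate")
  if (is.null(total_mapped)) total_mapped <- length(gr)
  read_set(gr, sample_id, total_mapped)
}

#' Write read intervals as BED
#'
#' @param rs a `read_set` or `GRanges`.
#' @param path output path.
#' @export
write_alignments <- function(rs, path) {
  gr <- if (is(rs, "GRanges")) rs else rs$reads
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a RepeatMasker-style repeat table
#'
#' Expects a tab-separated table with columns for chromosome, start, end and
#' repeat class/family (column names `chrom`/`genoName`, `start`/`genoStart`,
#' `end`/`genoEnd`, `re_class`/`repClass`/`class`, optionally
#' `re_name`/`repName`). Start/end follow the BED-style 0-based half-open
#' convention. Class strings are mapped onto [re_classes()] by prefix.
#'
#' @param path path to the table.
#' @return `GRanges` with metadata columns `re_class` (factor) and `re_name`.
#' @export
read_repeat_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  pick <- function(...) {
    nm <- intersect(c(...), names(df))
    if (length(nm)) df[[nm[1]]] else NULL
  }
  chrom <- pick("chrom", "genoName", "chr")
  start <- pick("start", "genoStart")
  end <- pick("end", "genoEnd")
  cls <- pick("re_class", "repClass", "class")
  if (is.null(chrom) || is.null(start) || is.null(end))
    stop("repeat table parse error: coordinate columns missing")
  if (is.null(cls)) stop("repeat table parse error: class column missing")
  if (any(end <= start)) stop("repeat table parse error: interval with end <= start")
  nm <- pick("re_name", "repName", "name")
  if (is.null(nm)) nm <- cls
  GRanges(chrom, IRanges(start + 1L, end),
          re_class = map_re_class(cls), re_name = as.character(nm))
}

#' Write a repeat track in the table layout read by [read_repeat_table()]
#'
#' @param track `GRanges` with `re_class` and `re_name` columns.
#' @param path output path.
#' @export
write_repeat_table <- function(track, path) {
  df <- data.frame(chrom = as.character(seqnames(track)),
                   start = start(track) - 1L, end = end(track),
                   re_class = as.character(track$re_class),
                   re_name = track$re_name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: set id, description, then member gene ids, all
#' tab-separated. Members are deduplicated within a set.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors with a `description` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- list()
    attr(out, "description") <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short))
    stop("GMT parse error: line ", which(short)[1], " has fewer than 3 fields")
  ids <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  attr(sets, "description") <- setNames(desc, ids)
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors (optionally with a
#'   `description` attribute as produced by [read_gene_sets()]).
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id)
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Remove exact positional duplicate reads
#'
#' Optional utility for inputs that have not gone through an upstream
#' duplicate-marking step; off by default in every pipeline entry point.
#' Keeps one read per (chrom, start, end, strand) tuple.
#'
#' @param rs a `read_set`.
#' @return a `read_set` with duplicates removed (`total_mapped` unchanged).
#' @export
dedup_reads <- function(rs) {
  gr <- rs$reads
  key <- paste(seqnames(gr), start(gr), end(gr), strand(gr))
  read_set(gr[!duplicated(key)], rs$sample_id, rs$total_mapped)
}
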