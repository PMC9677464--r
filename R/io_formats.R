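# Readers/writers for every external format the engine touches.
#
# Conventions used throughout: GFF3 coordinates are 1-based inclusive and all
# internal interval math keeps that convention; all TSVs are tab-delimited
# with a single `#`-prefixed header line; bin ids are deterministic.

#' Read a `#`-headered TSV with fixed columns
#'
#' Shared low-level reader: a tab-separated file whose first line may be a
#' `#`-prefixed header. Columns are matched by position against
#' `columns`.
#' @param path file path.
#' @param columns expected column names, in order.
#' @return data.frame with character columns named per `columns`.
#' @keywords internal
read_tsv_hash <- function(path, columns) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) && startsWith(lines[1], "#")) lines <- lines[-1]
  if (length(lines) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(columns)),
                                  columns))
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < length(columns)))
    stop("line ", which(nf < length(columns))[1], " of ", path, " has ",
         nf[which(nf < length(columns))[1]], " fields, expected ",
         length(columns))
  out <- as.data.frame(do.call(rbind, lapply(parts, `[`, seq_along(columns))),
                       stringsAsFactors = FALSE)
  names(out) <- columns
  out
}

#' Read assembly contigs from FASTA
#'
#' Sequences are uppercased; the contig id is the first whitespace-delimited
#' token of the header. Duplicate ids are a hard error.
#'
#' @param path FASTA file (gzip transparent).
#' @return named [Biostrings::DNAStringSet]; names are contig ids.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(seqs) == 0L) {
    warning("empty FASTA file: ", path)
    return(seqs)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate contig id(s) in ", path, ": ", paste(dup, collapse = ", "))
  names(seqs) <- ids
  Biostrings::DNAStringSet(toupper(as.character(seqs)))
}

# normalize a 2-column start/end matrix: sort, merge overlaps, clip to
# [1, len]; returns integer matrix with columns start, end (1-based inclusive)
normalize_intervals <- function(starts, ends, len = NULL) {
  if (length(starts) == 0L)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  if (!is.null(len)) {
    starts <- pmax(1L, as.integer(starts))
    ends <- pmin(as.integer(len), as.integer(ends))
    keep <- starts <= ends
    starts <- starts[keep]; ends <- ends[keep]
  }
  if (length(starts) == 0L)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  ir <- IRanges::reduce(IRanges::IRanges(start = starts, end = ends))
  cbind(start = IRanges::start(ir), end = IRanges::end(ir))
}

# low-level GFF3 line parser shared by the mask and RNA readers; returns a
# data.frame(seqid, type, start, end, attributes)
.parse_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  # Prokka-style GFF carries the assembly FASTA after "##FASTA"; readLines
  # already kept it, so cut at the first ">" record if present
  fasta_at <- which(startsWith(lines, ">"))
  if (length(fasta_at)) {
    lines <- lines[seq_len(fasta_at[1] - 1L)]
    lineno <- lineno[seq_along(lines)]
  }
  if (length(lines) == 0L)
    return(data.frame(seqid = character(0), type = character(0),
                      start = integer(0), end = integer(0),
                      attributes = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9L))
    stop("GFF3 line ", lineno[which(nf != 9L)[1]], " of ", path,
         " has ", nf[which(nf != 9L)[1]], " columns, expected 9")
  m <- do.call(rbind, parts)
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start) || anyNA(end))
    stop("non-numeric GFF3 coordinate at line ",
         lineno[which(is.na(start) | is.na(end))[1]], " of ", path)
  data.frame(seqid = m[, 1], type = m[, 3], start = start, end = end,
             attributes = m[, 9], stringsAsFactors = FALSE)
}

#' Extract maskable regions from a GFF3 annotation
#'
#' Returns, per contig, the merged 1-based inclusive intervals of features
#' whose type is in `mask_feature_types`. By default rRNA genes (barrnap)
#' and CRISPR `repeat_region` records (minced) are masked: rRNA is too
#' conserved and CRISPR spacers too foreign for their k-mers to resemble the
#' host genome. Strand is ignored; masking is strand-symmetric.
#'
#' @param path GFF3 file.
#' @param mask_feature_types feature types to mask.
#' @param contig_lengths optional named vector of contig lengths used to clip
#'   intervals to contig bounds; ids absent from it are retained as-is with a
#'   warning (the assembly join happens later).
#' @return named list: contig id -> integer matrix (columns `start`, `end`),
#'   sorted and overlap-merged.
#' @export
parse_gff_masks <- function(path,
                            mask_feature_types = c("rRNA", "repeat_region"),
                            contig_lengths = NULL) {
  gff <- .parse_gff3(path)
  gff <- gff[gff$type %in% mask_feature_types, , drop = FALSE]
  if (nrow(gff) == 0L) return(structure(list(), names = character(0)))
  if (!is.null(contig_lengths)) {
    unknown <- setdiff(unique(gff$seqid), names(contig_lengths))
    if (length(unknown))
      warning("GFF contig id(s) not in assembly: ",
              paste(unknown, collapse = ", "))
  }
  out <- lapply(split(gff, gff$seqid), function(g) {
    len <- if (!is.null(contig_lengths) && g$seqid[1] %in% names(contig_lengths))
      contig_lengths[[g$seqid[1]]] else NULL
    normalize_intervals(g$start, g$end, len)
  })
  out[order(names(out))]
}

#' Count unique tRNA isotypes and rRNA subunit types per contig
#'
#' tRNA uniqueness is keyed on the amino-acid isotype parsed from the
#' `product=tRNA-Xxx` attribute; rRNA types are drawn from \{5S, 16S, 23S\}
#' as matched in the product attribute. Used for MIMAG high-quality draft
#' tiering (>= 18 unique tRNAs, all three rRNAs).
#'
#' @param path GFF3 file with tRNA/rRNA features.
#' @return named list: contig id -> list(trna_isotypes = character vector,
#'   rrna_types = character vector).
#' @export
parse_gff_rna_counts <- function(path) {
  gff <- .parse_gff3(path)
  gff <- gff[gff$type %in% c("tRNA", "rRNA"), , drop = FALSE]
  if (nrow(gff) == 0L) return(structure(list(), names = character(0)))
  get_product <- function(attr) {
    m <- regmatches(attr, regexpr("product=[^;]*", attr))
    if (length(m) == 0L) NA_character_ else sub("^product=", "", m)
  }
  out <- lapply(split(gff, gff$seqid), function(g) {
    prods <- vapply(g$attributes, get_product, character(1), USE.NAMES = FALSE)
    if (anyNA(prods[g$type == "tRNA"]) || anyNA(prods[g$type == "rRNA"]))
      warning("RNA feature without product attribute on contig ", g$seqid[1],
              "; counted as non-unique")
    trna <- prods[g$type == "tRNA" & !is.na(prods)]
    iso <- regmatches(trna, regexpr("tRNA-[A-Za-z]{3}", trna))
    rrna <- prods[g$type == "rRNA" & !is.na(prods)]
    rtypes <- regmatches(rrna, regexpr("(5S|16S|23S)", rrna))
    list(trna_isotypes = sort(unique(iso)), rrna_types = sort(unique(rtypes)))
  })
  out[order(names(out))]
}

#' Read a per-sample average depth-of-coverage table
#'
#' Tab-separated; first column contig id, remaining columns one numeric
#' average depth per sample; an optional `#`-prefixed header carries sample
#' names. Contigs present in `contig_ids` but absent from the table get zero
#' depth with a warning (zero-coverage contigs do occur in real assemblies);
#' negative or non-numeric entries are errors.
#'
#' @param path TSV file.
#' @param contig_ids optional character vector to align/extend the table to.
#' @return numeric matrix, rownames contig ids, one column per sample.
#' @export
read_depth_table <- function(path, contig_ids = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  header <- NULL
  if (length(lines) && startsWith(lines[1], "#")) {
    header <- strsplit(sub("^#\\s*", "", lines[1]), "\t", fixed = TRUE)[[1]]
    lines <- lines[-1]
  }
  if (length(lines) == 0L) stop("empty depth table: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (length(unique(nf)) != 1L || nf[1] < 2L)
    stop("ragged or column-less depth table at line ",
         which(nf != nf[1])[1], " of ", path)
  ids <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate contig id in depth table: ",
         unique(ids[duplicated(ids)])[1])
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(parts, `[`, -1L))),
           nrow = length(parts), byrow = TRUE))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric depth at row ", bad[1], ", sample column ", bad[2],
         " of ", path)
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop("negative depth at row ", bad[1], ", sample column ", bad[2],
         " of ", path)
  }
  rownames(vals) <- ids
  colnames(vals) <- if (!is.null(header) && length(header) == ncol(vals) + 1L)
    header[-1] else paste0("sample_", seq_len(ncol(vals)))
  if (!is.null(contig_ids)) {
    missing <- setdiff(contig_ids, ids)
    if (length(missing)) {
      warning(length(missing), " contig(s) missing from depth table; ",
              "filled with zero depth")
      fill <- matrix(0, nrow = length(missing), ncol = ncol(vals),
                     dimnames = list(missing, colnames(vals)))
      vals <- rbind(vals, fill)
    }
    vals <- vals[contig_ids, , drop = FALSE]
  }
  vals
}

#' Read a marker-gene hit table
#'
#' Tab-separated rows of (contig_id, orf_id, marker_accession), one row per
#' hit; upstream annotation (ORF calling + HMM search) is out of scope here,
#' only its table is consumed.
#'
#' @param path TSV file.
#' @return data.frame with those three character columns.
#' @export
read_marker_hits <- function(path) {
  tab <- read_tsv_hash(path, c("contig_id", "orf_id", "marker_accession"))
  if (any(!nzchar(tab$marker_accession)))
    stop("empty marker accession in ", path)
  tab
}

#' Write accepted MAGs to disk
#'
#' Emits one FASTA per MAG (80-column wrap, named by bin id), a
#' contig-to-bin TSV and a per-run summary TSV. Bin FASTA content is exactly
#' the input contig sequences: masking only ever affects features, never
#' output sequence. Contigs must partition across MAGs.
#'
#' @param mags list of MAG objects (see [run_binny()]); each has `bin_id`,
#'   `contig_ids`, `quality`, plus acceptance provenance.
#' @param assembly named [Biostrings::DNAStringSet] with all contigs.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_bins <- function(mags, assembly, out_dir) {
  all_ids <- unlist(lapply(mags, `[[`, "contig_ids"))
  dup <- unique(all_ids[duplicated(all_ids)])
  if (length(dup))
    stop("contig(s) assigned to more than one MAG: ",
         paste(dup, collapse = ", "))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  c2b <- data.frame(contig_id = character(0), bin_id = character(0),
                    taxon = character(0), completeness = numeric(0),
                    purity = numeric(0), nc = logical(0), hq = logical(0))
  summary <- data.frame(bin_id = character(0), n_contigs = integer(0),
                        total_bp = numeric(0), taxon = character(0),
                        rank = character(0), completeness = numeric(0),
                        purity = numeric(0))
  for (mag in mags) {
    miss <- setdiff(mag$contig_ids, names(assembly))
    if (length(miss))
      stop("MAG ", mag$bin_id, " references unknown contig(s): ",
           paste(miss, collapse = ", "))
    seqs <- assembly[mag$contig_ids]
    fa <- file.path(out_dir, paste0(mag$bin_id, ".fasta"))
    Biostrings::writeXStringSet(seqs, fa, width = 80L)
    paths <- c(paths, fa)
    q <- mag$quality
    c2b <- rbind(c2b, data.frame(
      contig_id = mag$contig_ids, bin_id = mag$bin_id, taxon = q$taxon,
      completeness = q$completeness, purity = q$purity,
      nc = q$purity > 0.95 && q$completeness > 0.90,
      hq = q$purity > 0.90 && q$completeness > 0.70))
    summary <- rbind(summary, data.frame(
      bin_id = mag$bin_id, n_contigs = length(mag$contig_ids),
      total_bp = sum(Biostrings::width(seqs)), taxon = q$taxon,
      rank = q$rank, completeness = q$completeness, purity = q$purity))
  }
  c2b_path <- file.path(out_dir, "contig_to_bin.tsv")
  write_tsv_hash(c2b, c2b_path)
  sum_path <- file.path(out_dir, "bin_summary.tsv")
  write_tsv_hash(summary, sum_path)
  invisible(c(paths, c2b_path, sum_path))
}

#' @keywords internal
write_tsv_hash <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df))
    write.table(format(df, trim = TRUE, scientific = FALSE, digits = 15),
                con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}
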