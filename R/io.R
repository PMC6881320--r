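# Readers/writers for the formats the pipeline touches: annotation TSV
# (mirroring published mitogenome organization tables), GenBank flat files,
# FASTA, and the TSV/JSON report bundle.

#' Read an annotation table (TSV)
#'
#' One row per feature with columns `gene`, `class`, `start`, `end`,
#' `strand`, and optionally `start_codon`/`stop_codon` (header required;
#' extra columns ignored). Leading comment lines of the form
#' `# key=value` may carry `organism`, `genome_length` and `circular`;
#' explicit arguments override them. If the genome length is given nowhere,
#' the maximum feature end is used with a warning.
#'
#' @param path TSV file path.
#' @param organism,genome_length,circular optional overrides.
#' @return a `mito_annotation` (without sequence).
#' @export
read_annotation_tsv <- function(path, organism = NULL, genome_length = NULL,
                                circular = NULL) {
  lines <- readLines(path, n = 50L)
  meta <- list()
  for (ln in grep("^#", lines, value = TRUE)) {
    kv <- sub("^#\\s*", "", ln)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", kv))
      meta[[key]] <- trimws(sub("^[^=]*=", "", kv))
    }
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (is.null(organism)) organism <- meta$organism %||% ""
  if (is.null(genome_length)) {
    genome_length <- if (!is.null(meta$genome_length)) {
      as.integer(meta$genome_length)
    } else {
      warning("genome_length not given; using max feature end")
      max(df$end)
    }
  }
  if (is.null(circular)) {
    circular <- is.null(meta$circular) ||
      tolower(meta$circular) %in% c("true", "yes", "1")
  }
  genome_annotation(df, genome_length, organism = organism,
                    circular = circular)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an annotation table (TSV)
#'
#' Inverse of [read_annotation_tsv()]; also emits the derived `size_nt`,
#' `size_aa` and `intergenic` columns so the file mirrors a published
#' organization table. Negative spacers are written with an ASCII minus.
#'
#' @param g a `mito_annotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(g, path) {
  tab <- organization_table(g)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# organism=", g$organism),
               paste0("# genome_length=", g$genome_length),
               paste0("# circular=", tolower(as.character(g$circular)))), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Organization table of a genome (genes, coordinates, sizes, spacers)
#'
#' The per-genome report table: one row per feature with its coordinates,
#' span, encoded amino acids (PCGs), the signed intergenic spacer preceding
#' the gene on the circle, and the annotated codons.
#'
#' @param g a `mito_annotation`.
#' @return data.frame with columns `gene`, `class`, `start`, `end`,
#'   `strand`, `start_codon`, `stop_codon`, `size_nt`, `size_aa`,
#'   `intergenic`.
#' @export
organization_table <- function(g) {
  f <- g$features
  rep <- scan_spacers(g)
  # spacing before gene i = spacing of the pair whose downstream is gene i
  before <- rep$pairs$spacing[match(f$gene, rep$pairs$downstream)]
  span <- feature_length(f)
  aa <- ifelse(f$class == "PCG" & span %% 3L == 0L,
               span %/% 3L - 1L, NA_integer_)
  data.frame(f[, c("gene", "class", "start", "end", "strand",
                   "start_codon", "stop_codon")],
             size_nt = as.integer(span), size_aa = as.integer(aa),
             intergenic = as.integer(before), stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# GenBank flat files

# gene-symbol normalization: raw qualifier text -> the symbols used
# throughout this package (cox1, nad4l, trnL1, ...)
GENE_NAME_MAP <- c(
  cox1 = "cox1", coi = "cox1", co1 = "cox1", coxi = "cox1",
  cox2 = "cox2", coii = "cox2", co2 = "cox2", coxii = "cox2",
  cox3 = "cox3", coiii = "cox3", co3 = "cox3", coxiii = "cox3",
  atp6 = "atp6", atpase6 = "atp6", atp8 = "atp8", atpase8 = "atp8",
  nad1 = "nad1", nd1 = "nad1", nad2 = "nad2", nd2 = "nad2",
  nad3 = "nad3", nd3 = "nad3", nad4 = "nad4", nd4 = "nad4",
  nad4l = "nad4l", nd4l = "nad4l", nad5 = "nad5", nd5 = "nad5",
  nad6 = "nad6", nd6 = "nad6",
  cytb = "cytb", cob = "cytb", cyb = "cytb",
  rrns = "rrnS", rrnl = "rrnL", `12s` = "rrnS", `16s` = "rrnL",
  `s-rrna` = "rrnS", `l-rrna` = "rrnL",
  `12s ribosomal rna` = "rrnS", `16s ribosomal rna` = "rrnL",
  `small subunit ribosomal rna` = "rrnS",
  `large subunit ribosomal rna` = "rrnL"
)

AA3_TO_TRN <- c(ala = "A", arg = "R", asn = "N", asp = "D", cys = "C",
                gln = "Q", glu = "E", gly = "G", his = "H", ile = "I",
                leu = "L", lys = "K", met = "M", phe = "F", pro = "P",
                ser = "S", thr = "T", trp = "W", tyr = "Y", val = "V")

# internal: normalize a raw feature name/product; Leu/Ser tRNA isotypes are
# resolved from codon/anticodon hints in the text when present, otherwise
# left as trnL/trnS for ordinal disambiguation by the caller
normalize_gene_name <- function(raw) {
  x <- tolower(trimws(raw))
  if (x %in% names(GENE_NAME_MAP)) return(unname(GENE_NAME_MAP[[x]]))
  bare <- sub("\\s*\\(.*\\)$", "", x)
  if (bare %in% names(GENE_NAME_MAP)) return(unname(GENE_NAME_MAP[[bare]]))
  if (grepl("^trn[a-z][12]?$", x)) {
    return(paste0("trn", toupper(substr(x, 4L, 4L)), substr(x, 5L, 10L)))
  }
  m <- regmatches(x, regexec("trna[-_ ]([a-z]{3})", x))[[1L]]
  if (length(m) == 2L && m[2L] %in% names(AA3_TO_TRN)) {
    aa <- AA3_TO_TRN[[m[2L]]]
    iso <- ""
    if (aa %in% c("L", "S")) {
      hint <- regmatches(x, regexec("\\(([a-z]{3})\\)", x))[[1L]]
      if (length(hint) == 2L) {
        iso <- switch(hint[2L],
                      cta = "1", tag = "1", cun = "1",
                      tta = "2", taa = "2", uur = "2",
                      agc = "1", gct = "1", agn = "1",
                      tca = "2", tga = "2", ucn = "2", "")
      }
      if (iso == "" && grepl("(uur|2)", x)) iso <- if (aa == "L") "2" else "2"
      if (iso == "" && grepl("(cun|1)", x)) iso <- "1"
    }
    return(paste0("trn", aa, iso))
  }
  NA_character_
}

#' Read a GenBank flat file into a `mito_annotation`
#'
#' Parses LOCUS (length, topology), ORGANISM, the CDS/tRNA/rRNA features
#' (with `/gene` or `/product` qualifiers) and the ORIGIN sequence of a
#' standard GenBank record. Gene names are normalized to the lowercase
#' symbols used throughout the package (`ND4L` -> `nad4l`, `tRNA-Asp` ->
#' `trnD`, ...); Leu/Ser tRNA isotypes are resolved from anticodon hints
#' when present and by encounter order otherwise. Start/stop codons of
#' plus-frame CDS features are filled in from the sequence. Unmappable
#' features keep their raw name and are reported in the `findings`
#' attribute; a truncated record (no ORIGIN/terminator) is an error.
#'
#' @param path GenBank flat-file path.
#' @return a `mito_annotation` with sequence; attribute `findings` lists
#'   name-normalization issues.
#' @export
read_genbank_record <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^LOCUS", lines[1L])) {
    stop("not a GenBank flat file (no LOCUS line): ", path)
  }
  if (!any(grepl("^//\\s*$", lines))) {
    stop("truncated GenBank record (missing // terminator): ", path)
  }
  locus <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  genome_length <- as.integer(locus[3L])
  circular <- any(tolower(locus) == "circular")
  org_line <- grep("^\\s*ORGANISM", lines, value = TRUE)
  organism <- if (length(org_line) > 0L) {
    trimws(sub("^\\s*ORGANISM\\s*", "", org_line[1L]))
  } else ""
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart) == 0L) stop("GenBank record has no ORIGIN sequence: ", path)
  oend <- grep("^//\\s*$", lines)[1L]
  seq_lines <- lines[(ostart + 1L):(oend - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) != genome_length) {
    stop("ORIGIN sequence length (", nchar(sequence),
         ") disagrees with LOCUS length (", genome_length, ")")
  }
  fstart <- grep("^FEATURES", lines)
  if (length(fstart) == 0L) stop("GenBank record has no FEATURES table: ", path)
  flines <- lines[(fstart + 1L):(ostart - 1L)]
  keys <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA")
  feat_idx <- grep("^ {5}\\S", flines)
  rows <- list()
  findings <- list()
  counters <- new.env()
  for (k in seq_along(feat_idx)) {
    i <- feat_idx[k]
    j_end <- if (k < length(feat_idx)) feat_idx[k + 1L] - 1L else length(flines)
    header <- strsplit(trimws(flines[i]), "\\s+")[[1L]]
    key <- header[1L]
    if (!key %in% names(keys)) next
    loc <- header[2L]
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1L]])
    if (length(nums) < 2L) {
      findings[[length(findings) + 1L]] <- data.frame(
        code = "unparsable_location", raw = loc, stringsAsFactors = FALSE)
      next
    }
    qual_text <- paste(trimws(flines[i:j_end]), collapse = " ")
    get_qual <- function(q) {
      m <- regmatches(qual_text,
                      regexec(paste0("/", q, "=\"([^\"]*)\""), qual_text))[[1L]]
      if (length(m) == 2L) m[2L] else NA_character_
    }
    raw_name <- get_qual("gene")
    if (is.na(raw_name)) raw_name <- get_qual("product")
    name <- if (!is.na(raw_name)) normalize_gene_name(raw_name) else NA_character_
    # fold anticodon hints from the product into Leu/Ser isotypes
    if (!is.na(name) && name %in% c("trnL", "trnS")) {
      prod <- get_qual("product")
      hinted <- if (!is.na(prod)) normalize_gene_name(prod) else name
      if (!is.na(hinted) && nchar(hinted) == 5L) {
        name <- hinted
      } else {
        cnt <- get0(name, envir = counters, ifnotfound = 0L) + 1L
        assign(name, cnt, envir = counters)
        name <- paste0(name, cnt)
        findings[[length(findings) + 1L]] <- data.frame(
          code = "isotype_by_order", raw = raw_name, stringsAsFactors = FALSE)
      }
    }
    if (is.na(name)) {
      findings[[length(findings) + 1L]] <- data.frame(
        code = "unmappable_name", raw = raw_name %||% "<none>",
        stringsAsFactors = FALSE)
      name <- raw_name %||% paste0("feature", k)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene = name, class = unname(keys[key]),
      start = min(nums), end = max(nums), strand = strand,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no CDS/tRNA/rRNA features found: ", path)
  feats <- do.call(rbind, rows)
  feats$start_codon <- NA_character_
  feats$stop_codon <- NA_character_
  g <- genome_annotation(feats, genome_length, organism = organism,
                         circular = circular, sequence = sequence)
  # fill PCG codons from the sequence
  p <- which(g$features$class == "PCG")
  for (i in p) {
    s <- feature_sequence(g, g$features[i, ], strand = "gene")
    if (nchar(s) >= 6L) {
      g$features$start_codon[i] <- substr(s, 1L, 3L)
      g$features$stop_codon[i] <- substr(s, nchar(s) - 2L, nchar(s))
    }
  }
  attr(g, "findings") <- if (length(findings) > 0L) {
    do.call(rbind, findings)
  } else {
    data.frame(code = character(), raw = character(), stringsAsFactors = FALSE)
  }
  g
}

#' Write a `mito_annotation` as a GenBank flat file
#'
#' Emits a minimal standards-conforming record: LOCUS, DEFINITION, ORGANISM,
#' FEATURES (source plus gene/CDS/tRNA/rRNA with `/gene` qualifiers) and the
#' ORIGIN sequence in 60-base lines. Requires a sequence.
#'
#' @param g a `mito_annotation` with sequence.
#' @param path output path.
#' @param accession accession string for the LOCUS line.
#' @return `path`, invisibly.
#' @export
write_genbank_record <- function(g, path, accession = "SYN00001") {
  if (is.null(g$sequence)) stop("cannot write a GenBank record without sequence")
  con <- file(path, "w")
  on.exit(close(con))
  topo <- if (g$circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   INV %s",
                     accession, g$genome_length, topo,
                     format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(paste0("DEFINITION  ", g$organism,
                    " mitochondrion, complete genome."), con)
  writeLines("SOURCE      mitochondrion", con)
  writeLines(paste0("  ORGANISM  ", g$organism), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", g$genome_length), con)
  key_of <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA")
  f <- g$features
  for (i in seq_len(nrow(f))) {
    loc <- sprintf("%d..%d", f$start[i], f$end[i])
    if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-16s%s", key_of[[f$class[i]]], loc), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$gene[i]), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(g$sequence)
  starts <- seq(1L, nchar(s), by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, nchar(s)))
    blocks <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", st, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read/write genome FASTA
#'
#' Thin wrappers over Biostrings for whole-genome or gene-block FASTA files.
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
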