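#' Read annotated genomes from GenBank flat files
#'
#' Minimal GenBank flat-file reader covering the subset of the format needed
#' for regulon analysis: LOCUS records (several per file allowed), CDS
#' features with `join`-free locations on either strand, `/locus_tag`,
#' `/product` and `/translation` qualifiers, and the ORIGIN sequence block.
#' Draft (multi-contig) genomes are supported by listing several records or
#' files; genes are never joined across contigs downstream.
#'
#' @param paths character vector of GenBank file paths (all contigs of one
#'   species).
#' @param species_id species identifier attached to the genome.
#' @return A `genome` object: list with `species_id`, `contigs` (named list
#'   of DNA strings), `genes` (data.frame with `contig`, `locus_tag`,
#'   `start`, `end` (0-based half-open), `strand`, `product`, `protein`,
#'   sorted by contig then start) and `mono_freqs` (genome-wide A/C/G/T
#'   frequencies).
#' @export
read_genbank <- function(paths, species_id = basename(paths[1])) {
  records <- unlist(lapply(paths, split_genbank_records), recursive = FALSE)
  if (length(records) == 0L) stop("no GenBank records found", call. = FALSE)
  contigs <- list()
  gene_rows <- list()
  for (rec in records) {
    parsed <- parse_genbank_record(rec)
    if (is.null(parsed$sequence) || nchar(parsed$sequence) == 0L) {
      stop("GenBank record '", parsed$accession,
           "' has no ORIGIN sequence", call. = FALSE)
    }
    contigs[[parsed$accession]] <- parsed$sequence
    if (nrow(parsed$genes)) {
      parsed$genes$contig <- parsed$accession
      gene_rows[[length(gene_rows) + 1L]] <- parsed$genes
    }
  }
  genes <- if (length(gene_rows)) do.call(rbind, gene_rows) else
    data.frame(contig = character(0), locus_tag = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               product = character(0), protein = character(0))
  genes <- genes[order(match(genes$contig, names(contigs)), genes$start), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  # drop features that extend beyond their contig
  if (nrow(genes)) {
    clen <- nchar(unlist(contigs))[genes$contig]
    bad <- genes$end > clen | genes$start < 0
    if (any(bad)) {
      warning(sum(bad), " feature(s) beyond contig bounds skipped")
      genes <- genes[!bad, , drop = FALSE]
    }
  }
  genes <- fill_missing_translations(genes, contigs)
  new_genome(species_id, contigs, genes)
}

new_genome <- function(species_id, contigs, genes) {
  all_seq <- paste(unlist(contigs), collapse = "")
  counts <- vapply(DNA_BASES, function(b) {
    lengths(regmatches(all_seq, gregexpr(b, all_seq, fixed = TRUE)))
  }, numeric(1))
  freqs <- if (sum(counts) > 0) counts / sum(counts) else rep(0.25, 4)
  structure(list(species_id = species_id, contigs = contigs,
                 genes = genes, mono_freqs = freqs),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("Genome '%s': %d contig(s), %d genes, GC %.1f%%\n",
              x$species_id, length(x$contigs), nrow(x$genes),
              100 * sum(x$mono_freqs[c("C", "G")])))
  invisible(x)
}

split_genbank_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^//", lines)
  if (length(ends) == 0L) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  Map(function(s, e) lines[s:e], starts, ends)
}

parse_genbank_record <- function(lines) {
  locus_line <- grep("^LOCUS", lines, value = TRUE)
  accession <- if (length(locus_line)) {
    strsplit(trimws(sub("^LOCUS\\s+", "", locus_line[1])), "\\s+")[[1]][1]
  } else "unknown"
  feat_start <- grep("^FEATURES", lines)
  origin_start <- grep("^ORIGIN", lines)
  sequence <- NULL
  if (length(origin_start)) {
    seq_lines <- lines[(origin_start[1] + 1L):length(lines)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }
  genes <- data.frame(locus_tag = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      product = character(0), protein = character(0))
  if (length(feat_start)) {
    fend <- if (length(origin_start)) origin_start[1] - 1L else length(lines)
    flines <- lines[(feat_start[1] + 1L):fend]
    genes <- parse_feature_table(flines)
  }
  list(accession = accession, sequence = sequence, genes = genes)
}

parse_feature_table <- function(flines) {
  # feature keys start at column 6; qualifiers/continuations at column 22
  key_idx <- grep("^\\s{5}\\S", flines)
  rows <- list()
  for (k in seq_along(key_idx)) {
    i <- key_idx[k]
    j <- if (k < length(key_idx)) key_idx[k + 1L] - 1L else length(flines)
    parts <- strsplit(trimws(flines[i]), "\\s+")[[1]]
    key <- parts[1]
    if (key != "CDS") next
    block <- c(paste(parts[-1], collapse = ""), trimws(flines[setdiff(i:j, i)]))
    loc <- block[1]
    # continuation lines before the first qualifier extend the location
    qual_start <- grep("^/", block)
    if (length(qual_start) && qual_start[1] > 2L) {
      loc <- paste0(block[1:(qual_start[1] - 1L)], collapse = "")
    }
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- as.numeric(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
    if (length(nums) < 2L) next
    start1 <- min(nums); end1 <- max(nums)
    qlines <- if (length(qual_start)) {
      block[qual_start[1]:length(block)]
    } else character(0)
    quals <- parse_qualifiers(qlines)
    rows[[length(rows) + 1L]] <- data.frame(
      locus_tag = quals[["locus_tag"]] %||% sprintf("feat_%d", start1),
      start = as.integer(start1 - 1L), end = as.integer(end1),
      strand = strand,
      product = quals[["product"]] %||% "",
      protein = quals[["translation"]] %||% NA_character_,
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_tag = character(0), start = integer(0),
               end = integer(0), strand = character(0),
               product = character(0), protein = character(0))
}

parse_qualifiers <- function(qlines) {
  out <- list()
  current <- NULL
  for (ln in qlines) {
    if (grepl("^/", ln)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq > 0) {
        current <- substr(ln, 2L, eq - 1L)
        out[[current]] <- sub('^"', "", sub('"$', "", substr(ln, eq + 1L,
                                                             nchar(ln))))
      } else {
        current <- sub("^/", "", ln)
        out[[current]] <- TRUE
      }
    } else if (!is.null(current) && is.character(out[[current]])) {
      sep <- if (current == "translation") "" else " "
      out[[current]] <- paste0(out[[current]], sep, sub('"$', "", ln))
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fill_missing_translations <- function(genes, contigs) {
  if (!nrow(genes)) return(genes)
  need <- which(is.na(genes$protein))
  for (i in need) {
    cds <- substr(contigs[[genes$contig[i]]], genes$start[i] + 1L,
                  genes$end[i])
    if (genes$strand[i] == "-") cds <- revcomp(cds)
    genes$protein[i] <- translate_cds(cds)
  }
  genes
}

# Bacterial (table 11) translation of an in-frame CDS, stop trimmed.
translate_cds <- function(cds) {
  n <- nchar(cds) - nchar(cds) %% 3L
  if (n < 3L) return("")
  aa <- tryCatch(
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(cds, 1L, n)),
      genetic.code = Biostrings::getGeneticCode("11"),
      if.fuzzy.codon = "X")),
    error = function(e) "")
  sub("\\*$", "", aa)
}

#' Write a genome as a GenBank flat file
#'
#' Emits one minimal LOCUS record per contig (LOCUS / FEATURES with CDS
#' entries carrying locus_tag, product and translation / ORIGIN), in the
#' layout `read_genbank()` consumes. Used by the fixture generator so the
#' production parser is exercised end to end.
#'
#' @param genome a `genome` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (acc in names(genome$contigs)) {
    seq <- genome$contigs[[acc]]
    genes <- genome$genes[genome$genes$contig == acc, , drop = FALSE]
    writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   BCT", acc,
                       nchar(seq)), con)
    writeLines(sprintf("DEFINITION  synthetic genome %s.", genome$species_id),
               con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", nchar(seq)), con)
    for (i in seq_len(nrow(genes))) {
      loc <- sprintf("%d..%d", genes$start[i] + 1L, genes$end[i])
      if (genes$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"",
                         genes$locus_tag[i]), con)
      if (nzchar(genes$product[i])) {
        writeLines(sprintf("                     /product=\"%s\"",
                           genes$product[i]), con)
      }
      if (!is.na(genes$protein[i]) && nzchar(genes$protein[i])) {
        tr <- sprintf("/translation=\"%s\"", genes$protein[i])
        chunks <- substring(tr, seq(1L, nchar(tr), 58L),
                            pmin(seq(1L, nchar(tr), 58L) + 57L, nchar(tr)))
        writeLines(paste0("                     ", chunks), con)
      }
    }
    writeLines("ORIGIN", con)
    starts <- seq(1L, nchar(seq), 60L)
    for (s in starts) {
      chunk <- substr(seq, s, min(s + 59L, nchar(seq)))
      tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(1L, nchar(chunk), 10L) + 9L, nchar(chunk)))
      writeLines(sprintf("%9d %s", s, tolower(paste(tens, collapse = " "))),
                 con)
    }
    writeLines("//", con)
  }
  invisible(path)
}
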