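# Annotated plastome records: a circular uppercase DNA sequence plus
# normalized gene features. GenBank flat files are parsed directly (sequence,
# gene/CDS/tRNA/rRNA features, join/complement locations); no annotation is
# computed here, only ingested.

#' Construct an annotated genome
#'
#' @param id accession or sample identifier
#' @param seq uppercase DNA string over A,C,G,T,N (circular)
#' @param features list of gene features, see [gene_feature()]
#' @param source provenance string
#' @return an `annotated_genome` object
#' @export
annotated_genome <- function(id, seq, features = list(), source = "") {
  if (!nzchar(seq)) stop2("genome ", id, " has an empty sequence")
  seq <- toupper(seq)
  v <- seq_to_chars(seq)
  bad <- !(v %in% c(BASES, "N"))
  if (any(bad)) {
    message(sum(bad), " ambiguous base(s) mapped to N in ", id)
    v[bad] <- "N"
    seq <- chars_to_seq(v)
  }
  n <- nchar(seq)
  for (f in features) {
    if (any(f$exons < 0L) || any(f$exons > n))
      stop2("feature ", f$name, " lies outside [0, ", n, ") in ", id)
  }
  structure(list(id = id, seq = seq, features = features, source = source),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("annotated_genome ", x$id, ": ", nchar(x$seq), " bp, ",
      length(x$features), " features\n", sep = "")
  invisible(x)
}

#' Construct a gene feature
#'
#' Exons are 0-based half-open genome intervals, listed 5'->3' on the coding
#' strand (descending genome coordinates for minus-strand genes).
#'
#' @param name normalized gene symbol
#' @param kind one of "PCG", "tRNA", "rRNA"
#' @param strand "+" or "-"
#' @param exons integer matrix with columns start, end
#' @param copy copy index for genes duplicated in the inverted repeat
#' @return a `gene_feature` list
#' @export
gene_feature <- function(name, kind, strand, exons, copy = 1L) {
  stopifnot(kind %in% c("PCG", "tRNA", "rRNA"), strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, 2] <= exons[, 1]))
    stop2("feature ", name, ": empty or inverted exon interval")
  len <- sum(exons[, 2] - exons[, 1])
  structure(list(name = name, kind = kind, strand = strand, exons = exons,
                 copy = as.integer(copy), in_ir = FALSE,
                 non_canonical = (kind == "PCG" && len %% 3L != 0L)),
            class = "gene_feature")
}

feature_span <- function(f) range(f$exons)        # c(min start, max end)
feature_len <- function(f) sum(f$exons[, 2] - f$exons[, 1])

#' Normalize a plastid gene name
#'
#' Applies the conventional plastid casing (three-letter lowercase stem,
#' uppercase suffix letters: "RPOC2" -> "rpoC2", "YCF1" -> "ycf1"), keeps
#' tRNA anticodon suffixes uppercase ("trnh-gug" -> "trnH-GUG"), strips
#' whitespace, and finally applies the user-extensible synonym table shipped
#' with the package. The function is idempotent.
#'
#' @param raw character vector of raw gene names
#' @param synonyms optional two-column data frame (raw, normalized) of extra
#'   synonyms applied after the casing rules
#' @return normalized gene symbols
#' @export
normalize_gene_name <- function(raw, synonyms = NULL) {
  norm1 <- function(x) {
    x <- gsub("\\s+", "", x)
    if (!nzchar(x)) return(x)
    if (grepl("^trn", x, ignore.case = TRUE)) {
      # trnX or trnX-ABC (anticodon); the amino-acid letter and anticodon
      # are uppercase, the initiator-methionine prefix stays "fM"
      body <- toupper(substring(x, 4))
      body <- sub("^FM", "fM", body)
      return(paste0("trn", body))
    }
    if (nchar(x) <= 3) return(tolower(x))
    stem <- tolower(substring(x, 1, 3))
    rest <- seq_to_chars(substring(x, 4))
    isl <- grepl("[a-z]", rest, ignore.case = TRUE)
    rest[isl] <- toupper(rest[isl])
    paste0(stem, paste(rest, collapse = ""))
  }
  out <- vapply(raw, norm1, character(1), USE.NAMES = FALSE)
  tab <- gene_name_synonyms()
  if (!is.null(synonyms)) tab <- rbind(tab, synonyms[, 1:2])
  hit <- match(out, tab[[1]])
  out[!is.na(hit)] <- tab[[2]][hit[!is.na(hit)]]
  out
}

gene_name_synonyms <- function() {
  path <- system.file("extdata", "gene_name_synonyms.tsv", package = "plastdiv")
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

# ---- GenBank flat file parsing ---------------------------------------------

parse_gb_location <- function(loc) {
  # returns list(strand, exons [0-based half-open], ok); exons ordered 5'->3'
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc)) {
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  exons <- matrix(integer(0), ncol = 2)
  minus_parts <- FALSE
  for (p in parts) {
    st <- "+"
    if (grepl("^complement\\(", p)) {
      st <- "-"; minus_parts <- TRUE
      p <- sub("^complement\\((.*)\\)$", "\\1", p)
    }
    if (grepl("^\\d+\\.\\.\\d+$", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else if (grepl("^\\d+$", p)) {
      ab <- c(as.integer(p), as.integer(p))
    } else {
      return(list(ok = FALSE))
    }
    exons <- rbind(exons, c(ab[1] - 1L, ab[2]))  # to 0-based half-open
    if (st == "-") strand <- "-"
  }
  if (minus_parts) strand <- "-"
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  list(ok = TRUE, strand = strand, exons = exons)
}

#' Read an annotated genome from a GenBank flat file
#'
#' Extracts the sequence and the CDS/tRNA/rRNA feature records (gene records
#' are used only as a name fallback). Join and complement locations are
#' resolved; exon intervals become 0-based half-open; features duplicated in
#' the inverted repeat are retained with copy indices. Records with an
#' unparseable location are skipped with a warning and counted.
#'
#' @param path GenBank flat file
#' @return an `annotated_genome`
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  id <- basename(path)
  lv <- grep("^VERSION\\s+\\S", lines, value = TRUE)
  la <- grep("^ACCESSION\\s+\\S", lines, value = TRUE)
  if (length(lv)) id <- strsplit(trimws(sub("^VERSION", "", lv[1])), "\\s+")[[1]][1]
  else if (length(la)) id <- strsplit(trimws(sub("^ACCESSION", "", la[1])), "\\s+")[[1]][1]
  else {
    ll <- grep("^LOCUS\\s+\\S", lines, value = TRUE)
    if (length(ll)) id <- strsplit(trimws(sub("^LOCUS", "", ll[1])), "\\s+")[[1]][1]
  }

  io <- grep("^ORIGIN", lines)
  if (!length(io)) stop2("no ORIGIN/sequence section in ", path)
  seq_lines <- lines[(io[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(seq)) stop2("empty sequence in ", path)

  iff <- grep("^FEATURES", lines)
  features <- list()
  skipped <- 0L
  if (length(iff)) {
    fl <- lines[(iff[1] + 1):(io[1] - 1)]
    # feature keys start at column 6; qualifiers/continuations at column 22
    starts <- grep("^ {5}\\S", fl)
    kinds <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA")
    for (k in seq_along(starts)) {
      block <- fl[starts[k]:(if (k < length(starts)) starts[k + 1] - 1 else length(fl))]
      key <- sub("^\\s+", "", substring(block[1], 1, 20))
      key <- sub("\\s.*$", "", key)
      if (!key %in% names(kinds)) next
      # location may continue over lines until the first qualifier
      qual_at <- grep("^\\s{21}/", block)
      loc_end <- if (length(qual_at)) qual_at[1] - 1 else length(block)
      loc <- paste0(trimws(substring(block[1], 21)),
                    paste(trimws(block[seq_len(loc_end)][-1]), collapse = ""))
      gene <- NA_character_
      gl <- grep("^\\s{21}/gene=", block, value = TRUE)
      if (length(gl)) gene <- gsub("\"", "", sub("^\\s+/gene=", "", gl[1]))
      if (is.na(gene)) {
        pl <- grep("^\\s{21}/(product|label|standard_name)=", block, value = TRUE)
        if (length(pl)) gene <- gsub("\"", "", sub("^\\s+/[a-z_]+=", "", pl[1]))
      }
      if (is.na(gene)) gene <- paste0(key, "_", k)
      p <- parse_gb_location(loc)
      if (!isTRUE(p$ok)) {
        warning("skipping feature with unparseable location: ", gene, " [", loc, "]")
        skipped <- skipped + 1L
        next
      }
      if (any(p$exons > nchar(seq)))
        stop2("feature ", gene, " extends beyond the sequence in ", path)
      features[[length(features) + 1L]] <-
        gene_feature(normalize_gene_name(gene), kinds[[key]], p$strand, p$exons)
    }
  }
  features <- assign_copy_indices(features)
  if (skipped > 0L) message(skipped, " feature(s) skipped in ", path)
  annotated_genome(id, seq, features, source = path)
}

assign_copy_indices <- function(features) {
  if (!length(features)) return(features)
  nm <- vapply(features, `[[`, "", "name")
  for (u in unique(nm)) {
    idx <- which(nm == u)
    # deterministic copy order: by genome start coordinate
    ord <- order(vapply(features[idx], function(f) feature_span(f)[1], 0))
    for (j in seq_along(ord)) features[[idx[ord[j]]]]$copy <- j
  }
  features
}

#' Write an annotated genome as a GenBank flat file
#'
#' A minimal writer producing LOCUS/FEATURES/ORIGIN sections that
#' [read_genbank()] round-trips exactly (sequence and feature intervals).
#'
#' @param genome an `annotated_genome`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_genbank <- function(genome, path) {
  n <- nchar(genome$seq)
  out <- c(sprintf("LOCUS       %s %d bp    DNA     circular PLN", genome$id, n),
           sprintf("ACCESSION   %s", genome$id),
           sprintf("VERSION     %s", genome$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", n))
  keys <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA")
  for (f in genome$features) {
    ex <- f$exons
    if (f$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    locs <- sprintf("%d..%d", ex[, 1] + 1L, ex[, 2])
    loc <- if (length(locs) > 1) sprintf("join(%s)", paste(locs, collapse = ",")) else locs
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    out <- c(out,
             sprintf("     %-16s%s", keys[[f$kind]], loc),
             sprintf("                     /gene=\"%s\"", f$name))
  }
  out <- c(out, "ORIGIN")
  v <- tolower(genome$seq)
  starts <- seq(1, n, by = 60)
  for (s in starts) {
    chunk <- substring(v, s, min(s + 59, n))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(1, nchar(chunk), 10) + 9, nchar(chunk)))
    out <- c(out, sprintf("%9d %s", s, paste(blocks, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Extract the coding sequence of a feature
#'
#' Joins exons in coding order and reverse-complements minus-strand genes.
#' @param genome an `annotated_genome`
#' @param feature a `gene_feature`
#' @return CDS string, 5'->3'
#' @export
extract_cds <- function(genome, feature) {
  pieces <- apply(feature$exons, 1, function(e)
    substring(genome$seq, e[1] + 1L, e[2]))
  if (feature$strand == "-") pieces <- vapply(pieces, revcomp, character(1))
  paste(pieces, collapse = "")
}
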