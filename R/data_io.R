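#' Gene set container
#'
#' Minimal container for a named gene set (signature sets such as the iESR,
#' rESR or an Hsf1 regulon, GO-style annotation sets, TF target sets).
#' Members are deduplicated, order of first appearance is preserved.
#'
#' @param name Set name.
#' @param description One-line description (free text, may be `""`).
#' @param members Character vector of gene identifiers; must be non-empty.
#' @return An object of class `gene_set`: a list with elements `name`,
#'   `description`, `members`.
#' @export
gene_set <- function(name, description = "", members) {
  members <- unique(as.character(members))
  members <- members[nzchar(members)]
  if (length(members) == 0L) {
    stop("gene_set '", name, "' has no members")
  }
  structure(
    list(name = as.character(name), description = as.character(description),
         members = members),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, ": ", length(x$members), " genes\n", sep = "")
  invisible(x)
}

#' Position weight matrix container
#'
#' A column-stochastic 4 x L probability matrix over A, C, G, T together
#' with a background base composition. Built from count matrices (position
#' frequency matrices) via [read_jaspar_pfm()] or directly.
#'
#' @param tf_name Transcription factor name.
#' @param matrix Numeric 4 x L matrix with rownames A, C, G, T; every
#'   column must sum to 1 within 1e-9.
#' @param background Length-4 base frequency vector summing to 1
#'   (default uniform).
#' @return An object of class `pwm`.
#' @export
pwm <- function(tf_name, matrix, background = rep(0.25, 4)) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4L) stop("PWM matrix must have 4 rows (A,C,G,T)")
  if (ncol(matrix) < 1L) stop("PWM matrix must have at least one column")
  rownames(matrix) <- c("A", "C", "G", "T")
  cs <- colSums(matrix)
  if (any(abs(cs - 1) > 1e-9)) {
    stop("PWM '", tf_name, "': columns must sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")")
  }
  background <- as.numeric(background)
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9) {
    stop("background must be a length-4 frequency vector summing to 1")
  }
  structure(
    list(tf_name = as.character(tf_name), matrix = matrix,
         background = background),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$tf_name, ": width ", ncol(x$matrix), "\n", sep = "")
  invisible(x)
}

#' Read a count matrix with its sample annotation
#'
#' Reads a gene x sample TSV of non-negative integer counts (first column
#' gene identifiers, header row sample identifiers) together with a sample
#' annotation TSV with columns `sample_id`, `kinase`, `environment`,
#' `replicate`. Columns of the count matrix are reordered to the annotation
#' order. Gene and sample identifiers are treated as opaque, case-sensitive
#' strings.
#'
#' @param path Path to the count matrix TSV.
#' @param annotation_path Path to the sample annotation TSV.
#' @return A list with elements `counts` (integer matrix with gene rownames
#'   and sample colnames) and `annotation` (data.frame).
#' @export
read_count_matrix <- function(path, annotation_path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("count matrix must have a gene column and at least one sample")
  genes <- as.character(tab[[1L]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stop("duplicate gene ids in count matrix: ", paste(dup, collapse = ", "))
  }
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  bad <- which(!is.finite(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-integer or negative count at gene '", genes[bad[1L, 1L]],
         "', sample '", colnames(mat)[bad[1L, 2L]], "'")
  }
  storage.mode(mat) <- "integer"
  rownames(mat) <- genes

  ann <- utils::read.delim(annotation_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  validate_annotation(ann)
  missing <- setdiff(colnames(mat), ann$sample_id)
  if (length(missing)) {
    stop("samples absent from annotation: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(ann$sample_id, colnames(mat))
  if (length(extra)) {
    stop("annotated samples absent from count matrix: ",
         paste(extra, collapse = ", "))
  }
  mat <- mat[, ann$sample_id, drop = FALSE]
  list(counts = mat, annotation = ann)
}

#' Validate a sample annotation table
#'
#' Checks the design-table invariants: required columns, unique sample ids,
#' replicate >= 1, and (optionally) presence of at least one baseline
#' wild-type sample.
#'
#' @param ann Annotation data.frame.
#' @param baseline_strain,baseline_environment Baseline cell that must be
#'   present; set either to `NULL` to skip the check.
#' @return The annotation, invisibly. Errors describe the first violation.
#' @export
validate_annotation <- function(ann, baseline_strain = NULL,
                                baseline_environment = NULL) {
  need <- c("sample_id", "kinase", "environment", "replicate")
  absent <- setdiff(need, colnames(ann))
  if (length(absent)) {
    stop("annotation lacks column(s): ", paste(absent, collapse = ", "))
  }
  dup <- unique(ann$sample_id[duplicated(ann$sample_id)])
  if (length(dup)) stop("duplicate sample_id: ", paste(dup, collapse = ", "))
  if (any(!is.finite(ann$replicate) | ann$replicate < 1 |
          ann$replicate != round(ann$replicate))) {
    stop("replicate must be a positive integer")
  }
  if (!is.null(baseline_strain) && !is.null(baseline_environment)) {
    hit <- ann$kinase == baseline_strain & ann$environment == baseline_environment
    if (!any(hit)) {
      stop("no (", baseline_strain, ", ", baseline_environment,
           ") baseline sample in annotation")
    }
  }
  invisible(ann)
}

#' Write a count matrix and annotation as TSV
#'
#' @param counts Integer gene x sample matrix.
#' @param annotation Sample annotation data.frame.
#' @param path,annotation_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_count_matrix <- function(counts, annotation, path, annotation_path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(annotation, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, annotation_path))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members. Members repeated on a line are deduplicated.
#'
#' @param path Path to the GMT file.
#' @return A list of [gene_set()] objects in file order (possibly empty).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("GMT line ", i, " has fewer than 3 fields")
    }
    out[[i]] <- gene_set(fields[1L], fields[2L], fields[-(1:2)])
  }
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets List of [gene_set()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read position frequency matrices in JASPAR text format
#'
#' Parses blocks of the form `>ID NAME` followed by four rows of
#' non-negative counts for A, C, G, T (with or without the
#' `A [ 1 2 3 ]` row decoration). Counts are converted to column-stochastic
#' probabilities as `(count + pseudocount) / (colsum + 4 * pseudocount)`.
#'
#' @param path Path to the PFM text file.
#' @param pseudocount Pseudocount added to every cell (default 0.5, which
#'   keeps log-odds finite on zero counts).
#' @return A list of [pwm()] objects named by TF name.
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0.5) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no '>' header lines found in ", path)
  ends <- c(hdr[-1L] - 1L, length(lines))
  out <- list()
  for (b in seq_along(hdr)) {
    block <- lines[hdr[b]:ends[b]]
    toks <- strsplit(sub("^>\\s*", "", block[1L]), "\\s+")[[1L]]
    name <- if (length(toks) >= 2L) toks[2L] else toks[1L]
    rows <- block[-1L]
    if (length(rows) != 4L) {
      stop("PFM block '", name, "' must have exactly 4 count rows, found ",
           length(rows))
    }
    counts <- lapply(rows, function(r) {
      r <- gsub("^[ACGTacgt]\\s*", "", r)
      r <- gsub("[][]", " ", r)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(r), "\\s+")[[1L]]))
      if (anyNA(vals)) stop("unparseable count row in PFM block '", name, "'")
      vals
    })
    len <- unique(vapply(counts, length, integer(1)))
    if (length(len) != 1L) {
      stop("PFM block '", name, "': rows of unequal length")
    }
    cm <- do.call(rbind, counts)
    if (any(cm < 0)) stop("PFM block '", name, "': negative count")
    prob <- sweep(cm + pseudocount, 2L, colSums(cm) + 4 * pseudocount, "/")
    out[[name]] <- pwm(name, prob)
  }
  out
}

#' Write PWMs in JASPAR-like text PFM format
#'
#' Probabilities are written scaled to counts (x 100) so the file can be
#' round-tripped through [read_jaspar_pfm()] with `pseudocount = 0`.
#'
#' @param pwms List of [pwm()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_jaspar_pfm <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$tf_name, " ", p$tf_name), con)
    cm <- p$matrix * 100
    for (i in 1:4) {
      writeLines(paste0(rownames(cm)[i], " [ ",
                        paste(formatC(cm[i, ], format = "fg", digits = 8),
                              collapse = " "), " ]"), con)
    }
  }
  invisible(path)
}

#' Read promoter sequences from FASTA
#'
#' Record identifiers are gene identifiers; sequences are uppercased and
#' restricted to the alphabet A, C, G, T, N.
#'
#' @param path Path to the FASTA file.
#' @return Named character vector gene -> sequence.
#' @export
read_fasta_promoters <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate record ids in FASTA: ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[i]])
    if (bad > 0L) {
      stop("illegal character '", substr(seqs[[i]], bad, bad),
           "' in record '", ids[i], "' at position ", bad)
    }
  }
  seqs
}

#' Write promoter sequences to FASTA
#'
#' @param promoters Named character vector gene -> sequence.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta_promoters <- function(promoters, path) {
  ss <- Biostrings::DNAStringSet(promoters)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}
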