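#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric (one-sided Fisher) test of the overlap
#' between a query gene list and each annotation set, within a declared
#' universe, with Benjamini-Hochberg adjustment across sets. Query genes
#' outside the universe are dropped with a warning; set members are
#' intersected with the universe.
#'
#' @param query A [gene_set()] or character vector (e.g. the residual
#'   calls of one kinase in one environment).
#' @param sets List of [gene_set()]s.
#' @param universe A [gene_set()] or character vector of all assayable
#'   genes.
#' @param query_name Label recorded in the result (default the query's
#'   name, or `"query"`).
#' @return data.frame: query_name, set_name, k (overlap), n (query
#'   size), K (set size), N (universe size), p, padj.
#' @export
hypergeometric_enrichment <- function(query, sets, universe,
                                      query_name = NULL) {
  uni <- if (inherits(universe, "gene_set")) universe$members else
    unique(as.character(universe))
  if (length(uni) == 0L) stop("empty universe")
  q <- if (inherits(query, "gene_set")) query$members else
    unique(as.character(query))
  if (is.null(query_name)) {
    query_name <- if (inherits(query, "gene_set")) query$name else "query"
  }
  outside <- setdiff(q, uni)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    q <- intersect(q, uni)
  }
  N <- length(uni)
  n <- length(q)
  rows <- lapply(sets, function(s) {
    members <- intersect(s$members, uni)
    K <- length(members)
    k <- length(intersect(q, members))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(query_name = query_name, set_name = s$name, k = k, n = n,
               K = K, N = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$padj <- benjamini_hochberg(out$p)
  out
}

base_code <- function(seq) {
  # A=1 C=2 G=3 T=4, N=5
  chartr("ACGTN", "12345", seq)
}

#' Scan promoters with a position weight matrix
#'
#' Scores every window of every promoter on both strands with the
#' log2-odds of the PWM against a background base composition (by
#' default the empirical composition of the supplied promoters, in the
#' spirit of a 0-order background model). A gene is a hit when its best
#' window score reaches `score_threshold_fraction` times the maximum
#' achievable log-odds of the PWM. `N` bases contribute a log-odds of 0.
#'
#' @param promoters Named character vector gene -> sequence.
#' @param pwm A [pwm()].
#' @param score_threshold_fraction Fraction of the maximum achievable
#'   score required for a hit, in (0, 1] (default 0.8).
#' @param background Optional length-4 base frequency vector; default
#'   `NULL` uses the empirical promoter composition.
#' @return data.frame: gene, hit (logical), best_score, flag (`"ok"` or
#'   `"short"` for promoters shorter than the motif, scored as non-hits).
#' @export
scan_pwm <- function(promoters, pwm, score_threshold_fraction = 0.8,
                     background = NULL) {
  if (length(promoters) == 0L) stop("promoters must be non-empty")
  if (score_threshold_fraction <= 0 || score_threshold_fraction > 1) {
    stop("score_threshold_fraction must lie in (0, 1]")
  }
  w <- ncol(pwm$matrix)
  if (is.null(background)) {
    all_bases <- strsplit(paste(promoters, collapse = ""), "")[[1L]]
    tab <- table(factor(all_bases, levels = c("A", "C", "G", "T")))
    background <- as.numeric(tab) / sum(tab)
  }
  if (any(background <= 0)) stop("background frequencies must be positive")
  lom <- log2(pmax(pwm$matrix, 1e-12) / background)    # 4 x w
  lom <- rbind(lom, N = 0)                             # code 5 scores 0
  max_score <- sum(apply(lom[1:4, , drop = FALSE], 2L, max))
  thr <- score_threshold_fraction * max_score

  score_one <- function(seq) {
    L <- nchar(seq)
    if (L < w) return(NA_real_)
    codes <- as.integer(strsplit(base_code(seq), "")[[1L]])
    nwin <- L - w + 1L
    s <- numeric(nwin)
    for (j in seq_len(w)) {
      s <- s + lom[cbind(codes[j:(j + nwin - 1L)], j)]
    }
    max(s)
  }
  fwd <- vapply(promoters, score_one, numeric(1))
  rev <- vapply(revcomp(promoters), score_one, numeric(1))
  best <- pmax(fwd, rev)
  short <- is.na(best)
  hit <- !short & max_score > 0 & best >= thr
  data.frame(gene = names(promoters), hit = hit,
             best_score = ifelse(short, NA_real_, best),
             flag = ifelse(short, "short", "ok"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Promoter motif enrichment of residual-call gene groups
#'
#' Groups residual calls by (kinase, environment); for each group and
#' each PWM, tests by upper-tail hypergeometric whether the group's
#' genes are enriched for promoter hits of that motif relative to the
#' hit frequency in the universe, with BH adjustment across PWMs within
#' each group. Groups smaller than `min_genes` are skipped (recorded in
#' the `skipped` attribute).
#'
#' @param calls data.frame from [call_interactions()] (columns gene,
#'   kinase, environment).
#' @param promoters Named character vector gene -> sequence; must cover
#'   every called gene.
#' @param pwms Named list of [pwm()]s.
#' @param universe Character vector of genes defining the background
#'   (default all genes with promoters).
#' @param score_threshold_fraction Passed to [scan_pwm()] (default 0.8).
#' @param min_genes Minimum group size (default 5).
#' @return data.frame: kinase, environment, tf_name, k, n, K, N, p,
#'   padj; attribute `skipped` lists skipped groups.
#' @export
motif_enrichment <- function(calls, promoters, pwms,
                             universe = names(promoters),
                             score_threshold_fraction = 0.8,
                             min_genes = 5L) {
  missing <- setdiff(unique(calls$gene), names(promoters))
  if (length(missing)) {
    stop("no promoter supplied for gene(s): ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) " ..." else "")
  }
  universe <- intersect(universe, names(promoters))
  N <- length(universe)
  hits <- lapply(pwms, function(p) {
    sc <- scan_pwm(promoters[universe], p,
                   score_threshold_fraction = score_threshold_fraction)
    sc$gene[sc$hit]
  })
  groups <- split(calls$gene, paste(calls$kinase, calls$environment, sep = "@"))
  groups <- lapply(groups, unique)
  skipped <- names(groups)[vapply(groups, length, integer(1)) < min_genes]
  if (length(skipped)) {
    message("motif_enrichment: skipping ", length(skipped),
            " group(s) with fewer than ", min_genes, " genes")
  }
  groups <- groups[!names(groups) %in% skipped]
  out <- list()
  for (g in names(groups)) {
    genes <- intersect(groups[[g]], universe)
    parts <- strsplit(g, "@", fixed = TRUE)[[1L]]
    rows <- lapply(names(pwms), function(tf) {
      K <- length(hits[[tf]])
      k <- length(intersect(genes, hits[[tf]]))
      p <- stats::phyper(k - 1L, K, N - K, length(genes), lower.tail = FALSE)
      data.frame(kinase = parts[1L], environment = parts[2L], tf_name = tf,
                 k = k, n = length(genes), K = K, N = N, p = p,
                 stringsAsFactors = FALSE)
    })
    block <- do.call(rbind, rows)
    block$padj <- benjamini_hochberg(block$p)
    out[[g]] <- block
  }
  res <- if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
         else data.frame(kinase = character(), environment = character(),
                         tf_name = character(), k = integer(), n = integer(),
                         K = integer(), N = integer(), p = numeric(),
                         padj = numeric(), stringsAsFactors = FALSE)
  attr(res, "skipped") <- skipped
  res
}

#' Assemble the kinase -> TF bipartite network
#'
#' Keeps every (kinase, environment, TF) motif enrichment below the
#' adjusted-p cutoff as an edge and splits the edge list into
#' per-environment subgraphs for the focus environments plus a pooled
#' `"other"` graph for the rest.
#'
#' @param enrichments data.frame from [motif_enrichment()].
#' @param cutoff Adjusted-p cutoff (default 0.05).
#' @param focus_environments Environments given their own subgraph
#'   (default `c("heat_shock", "menadione")`).
#' @return List with `edges` (data.frame kinase, environment, tf_name,
#'   padj) and `subgraphs` (named list of edge data.frames, one per
#'   focus environment plus `"other"`).
#' @export
build_kinase_tf_network <- function(enrichments, cutoff = 0.05,
                                    focus_environments = c("heat_shock",
                                                           "menadione")) {
  edges <- enrichments[!is.na(enrichments$padj) & enrichments$padj < cutoff,
                       c("kinase", "environment", "tf_name", "padj"),
                       drop = FALSE]
  rownames(edges) <- NULL
  subgraphs <- list()
  for (e in focus_environments) {
    subgraphs[[e]] <- edges[edges$environment == e, , drop = FALSE]
  }
  subgraphs[["other"]] <-
    edges[!edges$environment %in% focus_environments, , drop = FALSE]
  list(edges = edges, subgraphs = subgraphs)
}
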