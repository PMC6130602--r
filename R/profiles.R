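#' Profile matrix constructor
#'
#' A `profile_matrix` is a binary genomes x genes matrix: entry `(g, q)` is 1
#' when gene family `q` is present in genome `g`. Columns may carry a
#' multiplicity (the number of original genes collapsed into a distinct
#' profile by [deduplicate_profiles()]) and a `members` list mapping each
#' column to the original gene ids it represents.
#'
#' @param mat binary matrix with genome ids as row names and gene/profile ids
#'   as column names.
#' @param multiplicity integer vector, one per column (default all 1).
#' @param members optional list of character vectors, one per column.
#' @return an object of class `"profile_matrix"`.
#' @export
profile_matrix <- function(mat, multiplicity = NULL, members = NULL) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("profile matrix needs genome row names and gene column names")
  if (!all(mat %in% c(0L, 1L))) stop("profile matrix entries must be 0/1")
  storage.mode(mat) <- "integer"
  if (is.null(multiplicity)) multiplicity <- setNames(rep(1L, ncol(mat)), colnames(mat))
  if (length(multiplicity) != ncol(mat)) stop("one multiplicity per column required")
  if (is.null(members)) members <- setNames(as.list(colnames(mat)), colnames(mat))
  structure(list(mat = mat, multiplicity = multiplicity, members = members),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d genomes x %d profiles (total multiplicity %d)\n",
              nrow(x$mat), ncol(x$mat), sum(x$multiplicity)))
  invisible(x)
}

#' @export
dim.profile_matrix <- function(x) dim(x$mat)

#' Read a homology hit table
#'
#' Reads BLAST/rapsearch-style tabular output (outfmt 6: qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore, no
#' header) and optionally maps subject sequence ids to genome ids via a
#' two-column TSV (`subject`, `genome`). Alternatively a headered TSV with at
#' least columns `query`, `genome`, `evalue` is accepted as-is.
#'
#' @param path hit table file.
#' @param genome_map optional two-column TSV mapping subject id to genome id.
#' @return data.frame with columns `query`, `genome`, `subject`, `evalue`,
#'   `bitscore` (where available).
#' @export
read_hits <- function(path, genome_map = NULL) {
  first <- readLines(path, n = 1L)
  headered <- grepl("query", first, fixed = TRUE)
  if (headered) {
    hits <- read.table(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE, quote = "")
  } else {
    raw <- read.table(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE, quote = "")
    if (ncol(raw) < 12) stop("expected >= 12 tab-separated columns (outfmt 6)")
    hits <- data.frame(query = raw[[1]], subject = raw[[2]],
                       evalue = raw[[11]], bitscore = raw[[12]],
                       stringsAsFactors = FALSE)
  }
  if (!is.null(genome_map)) {
    gm <- read.table(genome_map, header = FALSE, sep = "\t",
                     stringsAsFactors = FALSE, quote = "",
                     col.names = c("subject", "genome"))
    idx <- match(hits$subject, gm$subject)
    if (anyNA(idx)) stop("subjects missing from genome map: ",
                         paste(unique(hits$subject[is.na(idx)]), collapse = ", "))
    hits$genome <- gm$genome[idx]
  }
  if (!all(c("query", "genome", "evalue") %in% names(hits)))
    stop("hit table must provide query, genome and evalue")
  if (any(hits$evalue <= 0 & hits$evalue != 0))
    stop("negative e-value")
  hits
}

#' Assign per-query hit ranks
#'
#' When the hit table lacks an explicit rank, ranks are computed per query by
#' ascending e-value, ties broken by descending bitscore then lexical subject
#' id, so ranking is deterministic.
#'
#' @param hits data.frame with columns `query`, `evalue` and optionally
#'   `bitscore`, `subject`.
#' @return the hit table with a `rank` column.
#' @export
add_ranks <- function(hits) {
  if (!is.null(hits$rank)) return(hits)
  bs <- if (is.null(hits$bitscore)) rep(0, nrow(hits)) else hits$bitscore
  sj <- if (is.null(hits$subject)) rep("", nrow(hits)) else hits$subject
  hits$rank <- NA_integer_
  for (q in unique(hits$query)) {
    i <- which(hits$query == q)
    o <- order(hits$evalue[i], -bs[i], sj[i])
    hits$rank[i[o]] <- seq_along(i)
  }
  hits
}

#' Build presence/absence profiles from homology hits
#'
#' Entry `(g, q)` is set to 1 when some hit of query gene `q` against genome
#' `g` meets the e-value threshold, or when `g` is the query genome itself
#' (a gene is present in its source genome by definition). The default
#' threshold `1e-20` is applied inclusively (a hit exactly at the threshold
#' is admitted); set `inclusive = FALSE` for a strict comparison.
#'
#' @param hits hit table data.frame (`query`, `genome`, `evalue`).
#' @param genomes character vector of genome ids defining the rows.
#' @param query_genome id of the genome the query genes come from; must be in
#'   `genomes`.
#' @param evalue_max e-value threshold (default `1e-20`).
#' @param genes optional character vector of gene ids defining the columns
#'   (defaults to the queries observed in `hits`); genes with no hits get a
#'   self-presence-only column.
#' @param inclusive logical; admit hits with `evalue == evalue_max`?
#' @return a [profile_matrix()].
#' @export
build_profiles <- function(hits, genomes, query_genome, evalue_max = 1e-20,
                           genes = NULL, inclusive = TRUE) {
  stopifnot(evalue_max > 0, length(genomes) > 0)
  if (!query_genome %in% genomes) stop("query_genome must be among genomes")
  if (anyDuplicated(genomes)) stop("duplicate genome ids")
  if (nrow(hits) > 0) {
    bad <- setdiff(unique(hits$genome), genomes)
    if (length(bad)) stop("hits reference unknown genome(s): ",
                          paste(bad, collapse = ", "))
  } else {
    warning("empty hit table: profiles contain self-presence only")
  }
  if (is.null(genes)) genes <- sort(unique(hits$query))
  if (!length(genes)) stop("no genes: supply `genes` or a non-empty hit table")
  mat <- matrix(0L, length(genomes), length(genes),
                dimnames = list(genomes, genes))
  keep <- if (inclusive) hits$evalue <= evalue_max else hits$evalue < evalue_max
  hv <- hits[keep & hits$query %in% genes, , drop = FALSE]
  if (nrow(hv)) mat[cbind(match(hv$genome, genomes), match(hv$query, genes))] <- 1L
  mat[query_genome, ] <- 1L
  profile_matrix(mat)
}

#' Collapse identical profiles
#'
#' One column is kept per distinct 0/1 vector; its multiplicity is the number
#' of collapsed genes and `members` records their ids. Multiplicities of the
#' input columns are summed, so the operation is idempotent. The
#' representative id of a distinct profile is the lexically smallest member.
#'
#' @param pm a [profile_matrix()].
#' @return a deduplicated [profile_matrix()]; attribute `mapping` is a named
#'   character vector gene id -> distinct-profile id.
#' @export
deduplicate_profiles <- function(pm) {
  stopifnot(inherits(pm, "profile_matrix"))
  key <- apply(pm$mat, 2, paste0, collapse = "")
  groups <- split(seq_len(ncol(pm$mat)), key)
  reps <- vapply(groups, function(ix) {
    mem <- sort(unlist(pm$members[ix], use.names = FALSE))
    mem[1]
  }, character(1))
  ord <- order(reps)
  groups <- groups[ord]; reps <- reps[ord]
  mat <- pm$mat[, vapply(groups, `[`, integer(1), 1), drop = FALSE]
  colnames(mat) <- reps
  mult <- vapply(groups, function(ix) sum(pm$multiplicity[ix]), integer(1))
  members <- lapply(groups, function(ix) sort(unlist(pm$members[ix], use.names = FALSE)))
  names(mult) <- names(members) <- reps
  out <- profile_matrix(mat, mult, members)
  mapping <- unlist(lapply(seq_along(groups), function(k)
    setNames(rep(reps[k], length(members[[k]])), members[[k]])))
  attr(out, "mapping") <- mapping
  out
}

#' Uniformly subsample genomes and prune the tree to match
#'
#' Draws a uniformly random subset of `n` genomes that contains `keep`
#' (e.g. the focal genome), restricts the profile matrix rows to the subset
#' and prunes the tree to the same tips, suppressing degree-two nodes and
#' summing their branch lengths so pairwise patristic distances among the
#' retained tips are unchanged.
#'
#' @param pm a [profile_matrix()].
#' @param tree `"phylo"` whose tips include all matrix genomes.
#' @param n subset size, `n >= length(keep)`.
#' @param keep genome ids that must be retained.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return list with elements `profiles` and `tree`.
#' @export
subsample_taxa <- function(pm, tree, n, keep = character(), seed) {
  stopifnot(inherits(pm, "profile_matrix"))
  genomes <- rownames(pm$mat)
  if (!all(keep %in% genomes)) stop("keep genomes absent from the matrix")
  if (!all(genomes %in% tree$tip.label)) stop("tree tips must cover matrix genomes")
  if (n > length(genomes)) stop("n exceeds available genomes")
  if (n < length(keep)) stop("n smaller than the mandatory keep set")
  pool <- setdiff(genomes, keep)
  set.seed(as.integer(seed))
  chosen <- c(keep, sample(pool, n - length(keep)))
  chosen <- genomes[genomes %in% chosen]  # preserve input row order
  sub <- profile_matrix(pm$mat[chosen, , drop = FALSE], pm$multiplicity, pm$members)
  tr <- ape::keep.tip(tree, chosen)
  list(profiles = sub, tree = tr)
}

#' Flag genes with unexpected similarity to a target genome set
#'
#' A gene is flagged when at least one of its hits lands in a target genome
#' with e-value strictly below `evalue_max` and rank at most `rank_max`
#' among all of that gene's hits. The strict `<` mirrors the "unexpected
#' similarity" criterion used to detect candidate lateral-transfer partners;
#' set `inclusive = TRUE` for `<=`.
#'
#' @param hits hit table (`query`, `genome`, `evalue`, optional `rank`).
#' @param target_genomes genome ids of the putative transfer partner.
#' @param evalue_max e-value cutoff (strict by default).
#' @param rank_max maximal admissible rank (default 20).
#' @param inclusive logical; use `<=` on the e-value?
#' @return character vector of flagged gene ids.
#' @export
flag_unexpected_hits <- function(hits, target_genomes, evalue_max = 1e-20,
                                 rank_max = 20, inclusive = FALSE) {
  stopifnot(rank_max >= 1)
  if (!nrow(hits)) return(character())
  hits <- add_ranks(hits)
  ev_ok <- if (inclusive) hits$evalue <= evalue_max else hits$evalue < evalue_max
  sel <- hits$genome %in% target_genomes & ev_ok & hits$rank <= rank_max
  sort(unique(hits$query[sel]))
}

#' Identify informative profiles
#'
#' Profiles constant across the genomes (all present or all absent) carry no
#' signal for the correlated-evolution test and are excluded from pairwise
#' fitting.
#'
#' @param pm a [profile_matrix()].
#' @return logical vector, one per column, `TRUE` for non-constant profiles.
#' @export
informative_profiles <- function(pm) {
  cs <- colSums(pm$mat)
  ok <- cs > 0 & cs < nrow(pm$mat)
  setNames(ok, colnames(pm$mat))
}

#' Write / read a profile matrix as TSV
#'
#' Plain TSV with genomes as rows, genes as columns and 0/1 entries; column
#' multiplicities are stored in a `#multiplicity` comment line.
#'
#' @param pm a [profile_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(pm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#multiplicity\t",
                    paste(pm$multiplicity, collapse = "\t")), con)
  write.table(data.frame(genome = rownames(pm$mat), pm$mat,
                         check.names = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  lines <- readLines(path)
  multline <- grep("^#multiplicity", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#")]
  df <- read.table(text = body, header = TRUE, sep = "\t",
                   check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mult <- NULL
  if (length(multline)) {
    mult <- as.integer(strsplit(multline[1], "\t")[[1]][-1])
    names(mult) <- colnames(mat)
  }
  profile_matrix(mat, mult)
}
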