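# Sample-by-taxon count container consumed by all community statistics.

#' Construct a community count table
#'
#' @param counts samples x taxa matrix of non-negative integer counts
#'   (rownames samples, colnames taxon ids).
#' @param sample_days strictly increasing sampling day per row.
#' @param taxonomy data frame with columns `taxon_id`, `genus`, `phylum`;
#'   taxa missing from it are filled in as `"unclassified"`.
#' @param stages optional planted stage label per sample (carried through
#'   from the simulator).
#' @return object of class `community_table`.
#' @export
community_table <- function(counts, sample_days, taxonomy = NULL,
                            stages = NULL) {
  counts <- as.matrix(counts)
  if (any(is.na(counts))) stop("counts must not contain NA", call. = FALSE)
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg <- as.matrix(neg)) > 0)
    stop(sprintf("negative count at sample '%s', taxon '%s'",
                 rownames(counts)[neg[1, 1]] %||% neg[1, 1],
                 colnames(counts)[neg[1, 2]] %||% neg[1, 2]), call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers", call. = FALSE)
  if (length(sample_days) != nrow(counts))
    stop("sample_days length must match rows of counts", call. = FALSE)
  if (any(diff(sample_days) <= 0))
    stop("sample_days must be strictly increasing", call. = FALSE)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("d%02d", sample_days)
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("taxon_%04d", seq_len(ncol(counts)))
  tax <- data.frame(taxon_id = colnames(counts), genus = "unclassified",
                    phylum = "unclassified", stringsAsFactors = FALSE)
  if (!is.null(taxonomy)) {
    m <- match(tax$taxon_id, taxonomy$taxon_id)
    ok <- !is.na(m)
    tax$genus[ok] <- taxonomy$genus[m[ok]]
    tax$phylum[ok] <- taxonomy$phylum[m[ok]]
  }
  structure(list(counts = round(counts), sample_days = sample_days,
                 taxonomy = tax, stages = stages),
            class = "community_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.community_table <- function(x, ...) {
  cat("Community table:", nrow(x$counts), "samples x", ncol(x$counts),
      "taxa; reads/sample", paste(range(rowSums(x$counts)), collapse = "-"),
      "\n")
  invisible(x)
}

#' Relative abundances of a community table
#' @param table a [community_table()].
#' @return samples x taxa matrix of proportions (rows sum to 1).
#' @export
relative_abundance <- function(table) {
  tot <- rowSums(table$counts)
  if (any(tot == 0)) stop("sample with zero total reads", call. = FALSE)
  sweep(table$counts, 1, tot, "/")
}

#' Aggregate taxa to a taxonomic rank
#'
#' Sums counts of all taxa sharing a genus (or phylum); per-sample totals
#' are preserved.
#'
#' @param table a [community_table()].
#' @param rank `"genus"` or `"phylum"`.
#' @return a [community_table()] whose taxa are rank groups.
#' @export
aggregate_taxa <- function(table, rank = c("genus", "phylum")) {
  rank <- match.arg(rank)
  grp <- table$taxonomy[[rank]][match(colnames(table$counts),
                                      table$taxonomy$taxon_id)]
  agg <- t(rowsum(t(table$counts), grp))
  tax <- data.frame(taxon_id = colnames(agg), genus = NA_character_,
                    phylum = NA_character_, stringsAsFactors = FALSE)
  if (rank == "genus") {
    m <- match(colnames(agg), table$taxonomy$genus)
    tax$genus <- colnames(agg)
    tax$phylum <- table$taxonomy$phylum[m]
  } else {
    tax$genus <- "unclassified"
    tax$phylum <- colnames(agg)
  }
  community_table(agg, table$sample_days, tax, stages = table$stages)
}
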