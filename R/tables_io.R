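#' Construct a validated community table
#'
#' A community table holds an integer abundance matrix (taxa in rows, samples
#' in columns) together with a sample-to-region mapping, the standard layout
#' for rarefied amplicon (ASV) tables. All downstream analyses
#' ([regional_diversity()], the null models, the process partition) consume
#' this container.
#'
#' @param counts integer matrix, taxa x samples, with unique row and column
#'   names. All-zero taxon rows are permitted (and ignored by pooled
#'   statistics); all-zero sample columns are rejected.
#' @param sample_region named character vector mapping every sample id to a
#'   region label.
#' @param latitude optional named numeric vector of per-sample latitudes.
#' @return An object of class `community_table`: a list with elements
#'   `counts`, `sample_region` and `latitude`.
#' @seealso [read_community_table()], [rarefy()], [pool_region()]
#' @export
community_table <- function(counts, sample_region, latitude = NULL) {
  if (!is.matrix(counts)) stop("'counts' must be a matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have taxon row names and sample column names", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "),
         call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  zero_col <- colSums(counts) == 0L
  if (any(zero_col))
    stop("all-zero sample column(s): ",
         paste(colnames(counts)[zero_col], collapse = ", "), call. = FALSE)
  missing <- setdiff(colnames(counts), names(sample_region))
  if (length(missing))
    stop("sample(s) missing from metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  sample_region <- sample_region[colnames(counts)]
  if (!is.null(latitude)) {
    latitude <- latitude[colnames(counts)]
    names(latitude) <- colnames(counts)
  }
  structure(list(counts = counts,
                 sample_region = sample_region,
                 latitude = latitude),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d taxa x %d samples, %d region(s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$sample_region))))
  invisible(x)
}

#' Regions present in a community table
#' @param table a `community_table`.
#' @return character vector of region labels (unique, in order of appearance).
#' @export
regions <- function(table) unique(unname(table$sample_region))

region_sample_ids <- function(table, region) {
  if (!region %in% table$sample_region)
    stop("unknown region: ", region, call. = FALSE)
  names(table$sample_region)[table$sample_region == region]
}

#' Subset the count matrix of one region
#' @inheritParams regions
#' @param region region label.
#' @param drop_empty_taxa drop taxa absent from the region.
#' @return integer matrix, taxa x region samples.
#' @export
region_counts <- function(table, region, drop_empty_taxa = FALSE) {
  m <- table$counts[, region_sample_ids(table, region), drop = FALSE]
  if (drop_empty_taxa) m <- m[rowSums(m) > 0L, , drop = FALSE]
  m
}

#' Read a taxa-by-samples community table with sample metadata
#'
#' The table file is tab-delimited with a `taxon_id` first column and one
#' integer column per sample. The metadata file is tab-delimited with columns
#' `sample`, `region` and (optionally) `latitude`; every sample in the table
#' must appear in the metadata.
#'
#' @param path path to the community TSV.
#' @param metadata_path path to the metadata TSV.
#' @return a [community_table()].
#' @export
read_community_table <- function(path, metadata_path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("community table needs a taxon_id column plus >= 1 sample column",
         call. = FALSE)
  taxa <- as.character(raw[[1L]])
  m <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(raw[-1L], is.numeric, TRUE))[1L]
    stop(sprintf("non-numeric counts in column '%s'", names(raw)[-1L][bad]),
         call. = FALSE)
  }
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count (negative, missing or non-integer) at taxon '%s', sample '%s'",
                 taxa[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]), call. = FALSE)
  rownames(m) <- taxa
  meta <- read.delim(metadata_path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample", "region")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns 'sample' and 'region'", call. = FALSE)
  reg <- stats::setNames(as.character(meta$region), as.character(meta$sample))
  lat <- if ("latitude" %in% names(meta))
    stats::setNames(as.numeric(meta$latitude), as.character(meta$sample))
  community_table(m, reg, lat)
}

#' Write a community table (and optionally its metadata) to TSV
#' @inheritParams regions
#' @param path output path for the community TSV.
#' @param metadata_path optional output path for the metadata TSV.
#' @export
write_community_table <- function(table, path, metadata_path = NULL) {
  df <- data.frame(taxon_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  if (!is.null(metadata_path)) {
    meta <- data.frame(sample = colnames(table$counts),
                       region = unname(table$sample_region),
                       stringsAsFactors = FALSE)
    if (!is.null(table$latitude)) meta$latitude <- unname(table$latitude)
    write_tsv(meta, metadata_path)
  }
  invisible(path)
}

#' Rarefy a community table to a common depth
#'
#' Each sample column is subsampled without replacement (hypergeometric
#' rarefaction) to exactly `depth` individuals, the standard normalization
#' applied to amplicon tables before diversity analysis.
#'
#' @inheritParams regions
#' @param depth target number of individuals per sample.
#' @param seed integer seed; the subsampling is reproducible for a fixed seed.
#' @param drop_shallow if `TRUE`, samples whose total is below `depth` are
#'   dropped with a warning; the default is to error.
#' @return a rarefied `community_table` (every column sums to `depth`).
#' @export
rarefy <- function(table, depth, seed, drop_shallow = FALSE) {
  depth <- assert_scalar_int(depth, "depth")
  seed <- assert_scalar_int(seed, "seed", min = 0L)
  totals <- colSums(table$counts)
  shallow <- totals < depth
  if (any(shallow)) {
    if (!drop_shallow)
      stop("sample(s) below rarefaction depth ", depth, ": ",
           paste(colnames(table$counts)[shallow], collapse = ", "),
           call. = FALSE)
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(shallow), depth,
                    paste(colnames(table$counts)[shallow], collapse = ", ")))
  }
  m <- table$counts[, !shallow, drop = FALSE]
  withr::with_seed(seed, {
    out <- vapply(seq_len(ncol(m)), function(j) {
      col <- m[, j]
      if (sum(col) == depth) return(col)
      ids <- rep.int(seq_along(col), col)
      tabulate(ids[sample.int(length(ids), depth)], nbins = length(col))
    }, integer(nrow(m)))
  })
  dimnames(out) <- dimnames(m)
  community_table(out, table$sample_region[colnames(out)],
                  if (!is.null(table$latitude)) table$latitude[colnames(out)])
}

#' Summarize the regional species pool
#'
#' Pools all samples of one region: gamma (pooled richness), per-taxon
#' occurrence frequency (`sp_freq`, number of region samples containing the
#' taxon), pooled relative abundance, and per-sample richness and totals.
#' These are exactly the quantities the constrained null models and the
#' Raup-Crick null condition on.
#'
#' @inheritParams region_counts
#' @return an object of class `regional_pool` with elements `region`, `taxa`,
#'   `gamma`, `sp_freq`, `pool_rel_abund`, `samp_rich`, `samp_total`,
#'   `n_samples`.
#' @export
pool_region <- function(table, region) {
  m <- region_counts(table, region)
  if (ncol(m) < 2L) stop("region '", region, "' has fewer than 2 samples",
                         call. = FALSE)
  pooled <- rowSums(m)
  keep <- pooled > 0L
  sub <- m[keep, , drop = FALSE]
  structure(list(
    region         = region,
    taxa           = rownames(sub),
    gamma          = sum(keep),
    sp_freq        = rowSums(sub > 0L),
    pool_rel_abund = pooled[keep] / sum(pooled),
    samp_rich      = colSums(sub > 0L),
    samp_total     = colSums(sub),
    n_samples      = ncol(sub)
  ), class = "regional_pool")
}

#' @export
print.regional_pool <- function(x, ...) {
  cat(sprintf("regional_pool '%s': gamma = %d over %d samples\n",
              x$region, x$gamma, x$n_samples))
  invisible(x)
}

#' Read a numeric environmental table
#'
#' Tab-delimited, first column `sample`, remaining columns numeric variables
#' (e.g. pH, temperature, salinity). Missing values are rejected unless
#' `impute = TRUE`, in which case they are replaced by the variable mean.
#'
#' @param path path to the TSV.
#' @param impute mean-impute missing values instead of rejecting the file.
#' @return numeric matrix, samples x variables, with sample row names.
#' @export
read_env_table <- function(path, impute = FALSE) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(raw)[1L] != "sample")
    stop("environmental table must have 'sample' as its first column",
         call. = FALSE)
  m <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("environmental variables must be numeric", call. = FALSE)
  rownames(m) <- as.character(raw$sample)
  if (anyNA(m)) {
    if (!impute)
      stop("missing environmental values (use impute = TRUE to mean-impute)",
           call. = FALSE)
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      m[nas, j] <- mean(m[!nas, j])
    }
  }
  m
}

#' Read a rooted, branch-length-bearing phylogeny from newick
#' @param path newick file.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_phylogeny <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("phylogeny must have non-negative branch lengths", call. = FALSE)
  tree
}

#' Patristic (cophenetic) distance matrix of a phylogeny
#' @param tree a `phylo` object.
#' @param taxa optional taxon subset; every name must be a tip of the tree.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
patristic_distances <- function(tree, taxa = NULL) {
  d <- ape::cophenetic.phylo(tree)
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, rownames(d))
    if (length(missing))
      stop("taxa missing from phylogeny: ", paste(missing, collapse = ", "),
           call. = FALSE)
    d <- d[taxa, taxa, drop = FALSE]
  }
  d
}
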