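#' Combine per-sample CpG records into cohort count matrices
#'
#' Builds the cohort-level representation used for downstream analysis: a
#' methylated-count matrix `M` and a total-coverage matrix `Cov`, sites in
#' rows and samples in columns. The site set is the sorted union across
#' samples; a (site, sample) cell absent from a sample's input has
#' `Cov = 0`, `M = 0` — zero coverage, not a sentinel, encodes missingness,
#' and the beta at such a cell is undefined downstream.
#'
#' @param records_list List of CpG record tables, one per sample.
#' @param sample_ids Unique sample identifiers, parallel to `records_list`.
#' @return Object of class `methylation_matrix`: list with `sites`
#'   (data frame `chrom`, `pos`, sorted and unique), `samples`, integer
#'   matrices `M` and `Cov` (dimnames `chrom:pos` x sample id), and
#'   `sample_metadata` (`NULL` until [attach_metadata()]).
#' @examples
#' a <- cpg_records("chr1", 10L, 2L, 1L)
#' b <- cpg_records("chr1", 20L, 0L, 3L)
#' aggregate_samples(list(a, b), c("s1", "s2"))
#' @export
aggregate_samples <- function(records_list, sample_ids) {
  if (length(records_list) != length(sample_ids)) {
    stop("records_list and sample_ids must have the same length",
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("sample ids must be unique", call. = FALSE)
  }
  sample_ids <- as.character(sample_ids)
  keys_list <- vector("list", length(records_list))
  for (i in seq_along(records_list)) {
    r <- records_list[[i]]
    validate_cpg_records(r)
    key <- sprintf("%s:%d", r$chrom, r$pos)
    dup <- anyDuplicated(key)
    if (dup) {
      stop(sprintf("duplicate site %s in sample '%s'", key[dup],
                   sample_ids[i]), call. = FALSE)
    }
    keys_list[[i]] <- key
  }
  all_chrom <- unlist(lapply(records_list, `[[`, "chrom"), use.names = FALSE)
  all_pos <- unlist(lapply(records_list, `[[`, "pos"), use.names = FALSE)
  all_key <- sprintf("%s:%d", all_chrom, all_pos)
  first <- !duplicated(all_key)
  u_chrom <- all_chrom[first]
  u_pos <- all_pos[first]
  o <- site_order(u_chrom, u_pos)
  sites <- data.frame(chrom = u_chrom[o], pos = u_pos[o],
                      stringsAsFactors = FALSE)
  union_key <- sprintf("%s:%d", sites$chrom, sites$pos)
  n_sites <- nrow(sites)
  n_samples <- length(sample_ids)
  M <- matrix(0L, n_sites, n_samples,
              dimnames = list(union_key, sample_ids))
  Cov <- matrix(0L, n_sites, n_samples,
                dimnames = list(union_key, sample_ids))
  for (j in seq_along(records_list)) {
    r <- records_list[[j]]
    if (!nrow(r)) next
    i <- match(keys_list[[j]], union_key)
    M[i, j] <- r$count_meth
    Cov[i, j] <- r$count_meth + r$count_unmeth
  }
  structure(list(sites = sites, samples = sample_ids, M = M, Cov = Cov,
                 sample_metadata = NULL),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat("methylation_matrix: ", nrow(x$sites), " sites x ",
      length(x$samples), " samples\n", sep = "")
  cat("  samples: ", paste(utils::head(x$samples, 5), collapse = ", "),
      if (length(x$samples) > 5) ", ...", "\n", sep = "")
  cat("  metadata: ", if (is.null(x$sample_metadata)) "none" else
    paste(ncol(x$sample_metadata), "fields"), "\n", sep = "")
  invisible(x)
}

#' Attach per-sample QC metadata to a methylation matrix
#'
#' Joins the scalar fields of each sample's QC summary (read counts,
#' covered-CpG counts, conversion rate, ...) onto the matrix, in matrix
#' sample order.
#'
#' @param mat A `methylation_matrix`.
#' @param summaries List of `qc_summary` objects covering every matrix
#'   sample (extra summaries are ignored).
#' @return The matrix with `sample_metadata` populated.
#' @export
attach_metadata <- function(mat, summaries) {
  stopifnot(inherits(mat, "methylation_matrix"))
  ids <- vapply(summaries, function(s) s$sample_id, character(1))
  missing <- setdiff(mat$samples, ids)
  if (length(missing)) {
    stop("missing QC summary for sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(mat$samples, function(id) {
    f <- qc_scalar_fields(summaries[[match(id, ids)]])
    as.data.frame(f, stringsAsFactors = FALSE)
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(cols, names(r))) r[[nm]] <- NA
    r[cols]
  })
  mat$sample_metadata <- do.call(rbind, rows)
  rownames(mat$sample_metadata) <- NULL
  mat
}

matrix_to_tsv_lines <- function(m, samples) {
  header <- paste(c("site", samples), collapse = "\t")
  if (!nrow(m)) return(header)
  body <- paste(rownames(m),
                apply(m, 1L, paste, collapse = "\t"), sep = "\t")
  c(header, body)
}

df_to_tsv_lines <- function(df) {
  header <- paste(names(df), collapse = "\t")
  if (!nrow(df)) return(header)
  cells <- vapply(df, function(col) {
    out <- if (is.double(col)) {
      # 17 significant digits round-trips doubles exactly
      sprintf("%.17g", col)
    } else {
      as.character(col)
    }
    out[is.na(col)] <- "NA"
    out
  }, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  c(header, apply(cells, 1L, paste, collapse = "\t"))
}

#' Write / read a methylation matrix
#'
#' Two on-disk backends with identical logical content: `text` writes plain
#' TSVs (`sites.tsv`, `M.tsv`, `Cov.tsv`, optional `metadata.tsv`) for
#' portability; `chunked` writes column-major chunks of
#' `chunk_size` sites x all samples (plus the same sites/metadata TSVs) so
#' large cohorts can be streamed per sample without loading the full matrix.
#' Both round-trip exactly: `read_matrix(write_matrix(x))` equals `x`.
#'
#' @param mat A `methylation_matrix`.
#' @param path Output directory (created if needed).
#' @param backend `"text"` or `"chunked"`.
#' @param chunk_size Sites per chunk for the chunked backend.
#' @return `path` invisibly; `read_matrix()` returns the
#'   `methylation_matrix`.
#' @export
write_matrix <- function(mat, path, backend = c("text", "chunked"),
                         chunk_size = 10000L) {
  stopifnot(inherits(mat, "methylation_matrix"))
  backend <- match.arg(backend)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory: ", path,
                              call. = FALSE)
  manifest <- list(format = "bsqc-methylation-matrix", version = 1L,
                   backend = backend, n_sites = nrow(mat$sites),
                   samples = mat$samples,
                   has_metadata = !is.null(mat$sample_metadata))
  if (!is.null(mat$sample_metadata)) {
    manifest$metadata_classes <- vapply(mat$sample_metadata,
                                        function(col) class(col)[1],
                                        character(1))
  }
  write_text_lines(
    df_to_tsv_lines(mat$sites),
    file.path(path, "sites.tsv")
  )
  if (!is.null(mat$sample_metadata)) {
    write_text_lines(df_to_tsv_lines(mat$sample_metadata),
                     file.path(path, "metadata.tsv"))
  }
  if (backend == "text") {
    write_text_lines(matrix_to_tsv_lines(mat$M, mat$samples),
                     file.path(path, "M.tsv"))
    write_text_lines(matrix_to_tsv_lines(mat$Cov, mat$samples),
                     file.path(path, "Cov.tsv"))
  } else {
    chunk_dir <- file.path(path, "chunks")
    dir.create(chunk_dir, showWarnings = FALSE)
    n <- nrow(mat$M)
    starts <- seq(1L, max(n, 1L), by = chunk_size)
    if (n == 0L) starts <- integer() else starts <- starts[starts <= n]
    manifest$chunk_size <- as.integer(chunk_size)
    manifest$n_chunks <- length(starts)
    for (k in seq_along(starts)) {
      i0 <- starts[k]
      i1 <- min(i0 + chunk_size - 1L, n)
      saveRDS(list(M = mat$M[i0:i1, , drop = FALSE],
                   Cov = mat$Cov[i0:i1, , drop = FALSE]),
              file.path(chunk_dir, sprintf("chunk_%06d.rds", k)),
              compress = FALSE)
    }
  }
  write_text_lines(
    as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE)),
    file.path(path, "manifest.json")
  )
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) {
    stop("not a methylation matrix directory (no manifest.json): ", path,
         call. = FALSE)
  }
  manifest <- jsonlite::fromJSON(paste(read_text_lines(mf_path),
                                       collapse = "\n"))
  samples <- as.character(manifest$samples)
  sites_lines <- read_text_lines(file.path(path, "sites.tsv"))
  sites <- if (length(sites_lines) > 1L) {
    utils::read.table(text = sites_lines, sep = "\t", header = TRUE,
                      colClasses = c("character", "integer"),
                      stringsAsFactors = FALSE, quote = "")
  } else {
    data.frame(chrom = character(), pos = integer(),
               stringsAsFactors = FALSE)
  }
  key <- sprintf("%s:%d", sites$chrom, sites$pos)
  read_count_tsv <- function(file) {
    lines <- read_text_lines(file)
    if (length(lines) <= 1L) {
      return(matrix(0L, 0L, length(samples),
                    dimnames = list(NULL, samples)))
    }
    body <- strsplit(lines[-1L], "\t", fixed = TRUE)
    m <- matrix(as.integer(unlist(lapply(body, `[`, -1L))),
                nrow = length(body), byrow = TRUE)
    dimnames(m) <- list(vapply(body, `[[`, "", 1L), samples)
    m
  }
  if (manifest$backend == "text") {
    M <- read_count_tsv(file.path(path, "M.tsv"))
    Cov <- read_count_tsv(file.path(path, "Cov.tsv"))
  } else {
    n_chunks <- manifest$n_chunks
    chunks <- lapply(seq_len(n_chunks), function(k) {
      readRDS(file.path(path, "chunks", sprintf("chunk_%06d.rds", k)))
    })
    if (n_chunks) {
      M <- do.call(rbind, lapply(chunks, `[[`, "M"))
      Cov <- do.call(rbind, lapply(chunks, `[[`, "Cov"))
      colnames(M) <- samples
      colnames(Cov) <- samples
    } else {
      M <- matrix(0L, 0L, length(samples), dimnames = list(NULL, samples))
      Cov <- M
    }
  }
  stopifnot(identical(rownames(M), key) || nrow(M) == 0L)
  metadata <- NULL
  if (isTRUE(manifest$has_metadata)) {
    md_lines <- read_text_lines(file.path(path, "metadata.tsv"))
    classes <- unlist(manifest$metadata_classes)
    metadata <- utils::read.table(text = md_lines, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE,
                                  check.names = FALSE, quote = "",
                                  na.strings = "NA",
                                  colClasses = unname(classes))
  }
  structure(list(sites = sites, samples = samples, M = M, Cov = Cov,
                 sample_metadata = metadata),
            class = "methylation_matrix")
}
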