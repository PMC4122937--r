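#' Read contigs from a FASTA file
#'
#' Reads a (possibly gzipped) FASTA file into a contig tibble. Sequences are
#' uppercased and validated against the `A/C/G/T/N` alphabet; `U` (RNA) and
#' any other character are rejected with the offending record named. Record
#' order is preserved. Telomere columns are not set; see
#' [classify_contigs()].
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq`, `length`.
#' @seealso [write_fasta()], [classify_contigs()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- unname(toupper(as.character(ss)))
  check_dna(seqs, ids, context = "FASTA record")
  tibble(id = ids, seq = seqs, length = nchar(seqs))
}

#' Write contigs to a FASTA file
#'
#' Records are written in deterministic order, sorted by contig id (pass
#' `sort = FALSE` to keep input order).
#'
#' @param contigs Contig tibble with columns `id` and `seq`.
#' @param path Output path.
#' @param sort Sort records by id before writing (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, sort = TRUE) {
  stopifnot(all(c("id", "seq") %in% names(contigs)))
  if (sort) contigs <- arrange(contigs, .data$id)
  ss <- Biostrings::DNAStringSet(setNames(contigs$seq, contigs$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a pair of FASTQ files into a read-pair tibble
#'
#' Mate files must have equal record counts and matching ids (ignoring
#' trailing `/1`, `/2` or ` 1`, ` 2` suffixes); any mismatch is reported with
#' its record index. Per-base qualities are Phred+33 strings and must match
#' their sequence lengths.
#'
#' When `callback` is supplied the files are processed in chunks of
#' `chunk_size` pairs: the callback receives each chunk tibble in turn and
#' the function returns the list of callback results instead of one tibble,
#' so arbitrarily large libraries never need to be resident at once.
#'
#' @param path1,path2 Paths to the mate-1 and mate-2 FASTQ files (may be
#'   gzipped).
#' @param callback Optional function applied to each chunk tibble.
#' @param chunk_size Pairs per chunk when streaming (default 100000).
#' @return A tibble with columns `id`, `seq1`, `qual1`, `seq2`, `qual2`, or
#'   the list of callback results.
#' @export
read_fastq_pairs <- function(path1, path2, callback = NULL, chunk_size = 1e5) {
  for (p in c(path1, path2)) {
    if (!file.exists(p)) abort(sprintf("file not found: %s", p))
  }
  con1 <- file(path1, "r"); con2 <- file(path2, "r")
  on.exit({ close(con1); close(con2) }, add = TRUE)
  out <- list()
  done <- 0L
  repeat {
    l1 <- readLines(con1, n = 4L * chunk_size)
    l2 <- readLines(con2, n = 4L * chunk_size)
    if (length(l1) == 0L && length(l2) == 0L) break
    if (length(l1) != length(l2)) {
      abort(sprintf(
        "mate files have unequal record counts; first missing record at index %d",
        done + min(length(l1), length(l2)) %/% 4L + 1L
      ))
    }
    if (length(l1) %% 4L != 0L) abort("truncated FASTQ record (line count not a multiple of 4)")
    chunk <- parse_fastq_chunk(l1, l2, done)
    done <- done + nrow(chunk)
    if (is.null(callback)) out[[length(out) + 1L]] <- chunk
    else out[[length(out) + 1L]] <- callback(chunk)
  }
  if (is.null(callback)) {
    if (length(out) == 0L) {
      return(tibble(id = character(), seq1 = character(), qual1 = character(),
                    seq2 = character(), qual2 = character()))
    }
    bind_rows(out)
  } else {
    out
  }
}

parse_fastq_chunk <- function(l1, l2, offset) {
  i <- seq(1L, length(l1), by = 4L)
  id1 <- sub("[/ ][12]$", "", sub("^@", "", sub("\\s.*$", "", l1[i])))
  id2 <- sub("[/ ][12]$", "", sub("^@", "", sub("\\s.*$", "", l2[i])))
  bad <- which(id1 != id2)
  if (length(bad)) {
    abort(sprintf("mate ids disagree at record %d: '%s' vs '%s'",
                  offset + bad[1], id1[bad[1]], id2[bad[1]]))
  }
  s1 <- toupper(l1[i + 1L]); s2 <- toupper(l2[i + 1L])
  q1 <- l1[i + 3L]; q2 <- l2[i + 3L]
  len_bad <- which(nchar(s1) != nchar(q1) | nchar(s2) != nchar(q2) |
                     nchar(s1) == 0L | nchar(s2) == 0L)
  if (length(len_bad)) {
    abort(sprintf("sequence/quality length mismatch for read '%s'", id1[len_bad[1]]))
  }
  check_dna(s1, id1, "read"); check_dna(s2, id2, "read")
  tibble(id = id1, seq1 = s1, qual1 = q1, seq2 = s2, qual2 = q2)
}

#' Write a read-pair tibble as two FASTQ files
#'
#' @param pairs Read-pair tibble (`id`, `seq1`, `qual1`, `seq2`, `qual2`).
#' @param path1,path2 Output paths; a `.gz` suffix gzips the file.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  write_one <- function(ids, seqs, quals, suffix, path) {
    lines <- as.vector(rbind(paste0("@", ids, suffix), seqs, "+", quals))
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    writeLines(lines, con)
  }
  write_one(pairs$id, pairs$seq1, pairs$qual1, "/1", path1)
  write_one(pairs$id, pairs$seq2, pairs$qual2, "/2", path2)
  invisible(c(path1, path2))
}

#' Write fragmentation sites as BED
#'
#' Emits BED6 with 0-based half-open single-base intervals: name is the end
#' sense (`left`/`right`), score the supporting-read count, strand `+` for
#' left (C-rich) junctions and `-` for right (G-rich) junctions. Rows are
#' sorted by contig id then coordinate.
#'
#' @param sites Fragmentation-site tibble from [call_fragmentation_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- sites %>%
    arrange(.data$contig_id, .data$position) %>%
    mutate(
      start = .data$position, end = .data$position + 1L,
      strand = if_else(.data$end_sense == "left", "+", "-")
    ) %>%
    select("contig_id", "start", "end", name = "end_sense",
           score = "support", "strand")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read fragmentation sites from BED
#'
#' @param path BED file written by [write_sites_bed()].
#' @return Tibble with columns `contig_id`, `position`, `end_sense`,
#'   `support`.
#' @export
read_sites_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("contig_id", "start", "end",
                                             "name", "score", "strand"),
                         col_types = "ciicic", progress = FALSE)
  tibble(contig_id = bed$contig_id, position = bed$start,
         end_sense = bed$name, support = bed$score)
}

#' Write pipeline objects to standard formats
#'
#' Thin dispatcher over the format-specific writers, with deterministic
#' output ordering throughout.
#'
#' @param x Object to write: a contig tibble (FASTA), any tibble (TSV), or a
#'   fragmentation-site tibble (BED).
#' @param path Output path.
#' @param format One of `"fasta"`, `"tsv"`, `"bed"`.
#' @return `path`, invisibly.
#' @export
write_outputs <- function(x, path, format = c("fasta", "tsv", "bed")) {
  format <- match.arg(tolower(format), c("fasta", "tsv", "bed"))
  switch(format,
    fasta = write_fasta(x, path),
    bed = write_sites_bed(x, path),
    tsv = {
      if (all(c("contig_id", "position") %in% names(x))) {
        x <- arrange(x, .data$contig_id, .data$position)
      } else if ("contig_id" %in% names(x)) {
        x <- arrange(x, .data$contig_id)
      } else if ("id" %in% names(x)) {
        x <- arrange(x, .data$id)
      }
      readr::write_tsv(x, path)
      invisible(path)
    }
  )
}

#' Assemble a run configuration
#'
#' Bundles the tunables of every pipeline stage into one serializable
#' object, so a run can be reproduced from its manifest alone.
#'
#' @param telomere,sim,mapper,extension,merge,fragsite Parameter objects from
#'   the respective constructors; defaults are used where omitted.
#' @param seed Integer seed governing all randomness.
#' @return A `nanoterm_config` list.
#' @seealso [write_config()], [read_config()], [write_manifest()]
#' @export
run_config <- function(telomere = telomere_spec(), sim = sim_params(),
                       mapper = mapper_params(), extension = extension_params(),
                       merge = merge_params(), fragsite = fragsite_params(),
                       seed = 1L) {
  structure(list(telomere = telomere, sim = sim, mapper = mapper,
                 extension = extension, merge = merge, fragsite = fragsite,
                 seed = as.integer(seed)),
            class = "nanoterm_config")
}

#' @rdname run_config
#' @param config A `nanoterm_config` object.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x) {
    if (is.list(x)) unclass(x) else x
  }), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  run_config(
    telomere = do.call(telomere_spec, raw$telomere %||% list()),
    sim = do.call(sim_params, raw$sim %||% list()),
    mapper = do.call(mapper_params, raw$mapper %||% list()),
    extension = do.call(extension_params, raw$extension %||% list()),
    merge = do.call(merge_params, raw$merge %||% list()),
    fragsite = do.call(fragsite_params, raw$fragsite %||% list()),
    seed = raw$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' Records the fully resolved configuration, seed, package version and
#' timestamp alongside a run's outputs.
#'
#' @param dir Output directory (created if needed).
#' @param config A `nanoterm_config`.
#' @param extra Optional named list of additional fields (input/output
#'   counts, stage logs).
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, extra = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "manifest.yaml")
  payload <- c(
    list(package = "nanoterm",
         version = as.character(utils::packageVersion("nanoterm")),
         config = lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)),
    extra
  )
  yaml::write_yaml(payload, path)
  invisible(path)
}
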