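# Seeded randomness that never disturbs the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a random genome sequence
#'
#' I.i.d. bases at a requested GC fraction; fully determined by `seed`.
#'
#' @param length number of bases.
#' @param gc GC fraction in `[0, 1]` (default 0.41, human-like).
#' @param seed integer seed.
#' @return a character scalar over A/C/G/T.
#' @examples
#' random_genome(20, seed = 1)
#' @export
random_genome <- function(length, gc = 0.41, seed = 1L) {
  stopifnot(length >= 0, gc >= 0, gc <= 1)
  if (length == 0) return("")
  codes <- c(65L, 67L, 71L, 84L)  # A C G T
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  with_seed(seed,
            intToUtf8(codes[sample.int(4L, length, replace = TRUE,
                                       prob = prob)]))
}

#' Mutation model for synthetic mutant genomes
#'
#' Describes the divergence between a reference and a simulated individual:
#' point substitutions, short insertions/deletions with geometric lengths,
#' and runs of `N` replacing stretches of known sequence (unknown-base
#' stretches typical of assembled genomes). The default substitution rate
#' of 1e-3 emulates the ~99.9% identity of two genomes of the same
#' (human-like) species; rates of 1e-2 and above emulate the more divergent
#' regime where referential compression degrades.
#'
#' @param snp_rate substitutions per base.
#' @param indel_rate indel events per base; lengths are geometric with mean
#'   `indel_mean`, insertions and deletions equally likely.
#' @param indel_mean mean indel length (>= 1).
#' @param n_run_rate N-run events per base; each replaces a geometric-length
#'   (mean `n_run_mean`) stretch with `N`s.
#' @param n_run_mean mean N-run length (>= 1).
#' @param seed integer seed; identical model (incl. seed) gives an
#'   identical mutant.
#' @return an object of class `mutation_model`.
#' @export
mutation_model <- function(snp_rate = 1e-3, indel_rate = 1e-4,
                           indel_mean = 3, n_run_rate = 1e-6,
                           n_run_mean = 100, seed = 1L) {
  rates <- c(snp_rate, indel_rate, n_run_rate)
  stopifnot(all(rates >= 0), all(rates <= 1), indel_mean >= 1,
            n_run_mean >= 1)
  structure(list(snp_rate = snp_rate, indel_rate = indel_rate,
                 indel_mean = indel_mean, n_run_rate = n_run_rate,
                 n_run_mean = n_run_mean, seed = as.integer(seed)),
            class = "mutation_model")
}

#' @export
print.mutation_model <- function(x, ...) {
  cat(sprintf("mutation model: snp %.2g/bp, indel %.2g/bp (mean %g), N-run %.2g/bp (mean %g), seed %d\n",
              x$snp_rate, x$indel_rate, x$indel_mean, x$n_run_rate,
              x$n_run_mean, x$seed))
  invisible(x)
}

BASE_CODES <- charToRaw("ACGT")

#' Mutate a reference into a synthetic individual
#'
#' Applies, in this order: point substitutions (a different base, drawn
#' uniformly), N-run replacements, and indels (spliced from right to left
#' so event positions stay in reference coordinates). Every event is
#' recorded with position and payload, and replaying the log with
#' [apply_events()] reproduces the mutant exactly.
#'
#' @param reference a character scalar.
#' @param model a [mutation_model()].
#' @return list with `mutant` (character scalar) and `events` (data.frame
#'   with columns `type` in snp/nrun/ins/del, `pos` 1-based reference
#'   position, `ref`, `alt`).
#' @export
mutate <- function(reference, model = mutation_model()) {
  stopifnot(is.character(reference), length(reference) == 1,
            inherits(model, "mutation_model"))
  n <- nchar(reference)
  with_seed(model$seed, {
    rr <- charToRaw(reference)
    ev <- list()

    # substitutions: only ACGT positions are eligible
    if (model$snp_rate > 0 && n > 0) {
      pos <- which(runif(n) < model$snp_rate)
      pos <- pos[rr[pos] %in% BASE_CODES]
      if (length(pos) > 0) {
        cur <- match(rr[pos], BASE_CODES)
        alt <- BASE_CODES[(cur - 1L + sample.int(3L, length(pos),
                                                 replace = TRUE)) %% 4L + 1L]
        ev$snp <- data.frame(type = "snp", pos = pos,
                             ref = strsplit(rawToChar(rr[pos]), "")[[1]],
                             alt = strsplit(rawToChar(alt), "")[[1]],
                             stringsAsFactors = FALSE)
        rr[pos] <- alt
      }
    }

    # N-runs replace stretches in place (coordinates preserved)
    if (model$n_run_rate > 0 && n > 0) {
      pos <- which(runif(n) < model$n_run_rate)
      if (length(pos) > 0) {
        len <- pmin(rgeom(length(pos), 1 / model$n_run_mean) + 1L,
                    n - pos + 1L)
        keep <- !logical(length(pos))
        last_end <- -1
        for (k in seq_along(pos)) {        # drop overlapping runs
          if (pos[k] <= last_end) keep[k] <- FALSE
          else last_end <- pos[k] + len[k] - 1L
        }
        pos <- pos[keep]; len <- len[keep]
        if (length(pos) > 0) {
          refs <- substring(rawToChar(rr), pos, pos + len - 1L)
          for (k in seq_along(pos))
            rr[seq(pos[k], pos[k] + len[k] - 1L)] <- charToRaw("N")
          ev$nrun <- data.frame(type = "nrun", pos = pos, ref = refs,
                                alt = strrep("N", len),
                                stringsAsFactors = FALSE)
        }
      }
    }

    # indels, applied in one left-to-right splice over the raw vector
    if (model$indel_rate > 0 && n > 0) {
      pos <- which(runif(n) < model$indel_rate)
      if (length(pos) > 0) {
        is_ins <- runif(length(pos)) < 0.5
        len <- rgeom(length(pos), 1 / model$indel_mean) + 1L
        len <- pmin(len, ifelse(is_ins, len, n - pos + 1L))
        # deletions must not overlap the next event
        del_end <- ifelse(is_ins, pos, pos + len - 1L)
        keep <- !logical(length(pos))
        last_end <- -1
        for (k in seq_along(pos)) {
          if (pos[k] <= last_end) keep[k] <- FALSE
          else last_end <- del_end[k]
        }
        pos <- pos[keep]; is_ins <- is_ins[keep]; len <- len[keep]
        if (length(pos) > 0) {
          ins_seq <- vapply(len, function(l)
            rawToChar(BASE_CODES[sample.int(4L, l, replace = TRUE)]),
            character(1))
          pieces <- vector("list", 2L * length(pos) + 1L)
          rows <- vector("list", length(pos))
          prev <- 1L
          for (k in seq_along(pos)) {
            pieces[[2L * k - 1L]] <- if (pos[k] > prev)
              rr[prev:(pos[k] - 1L)] else raw(0)
            if (is_ins[k]) {
              pieces[[2L * k]] <- charToRaw(ins_seq[k])
              rows[[k]] <- data.frame(type = "ins", pos = pos[k], ref = "",
                                      alt = ins_seq[k],
                                      stringsAsFactors = FALSE)
              prev <- pos[k]
            } else {
              pieces[[2L * k]] <- raw(0)
              rows[[k]] <- data.frame(
                type = "del", pos = pos[k],
                ref = rawToChar(rr[pos[k]:(pos[k] + len[k] - 1L)]),
                alt = "", stringsAsFactors = FALSE)
              prev <- pos[k] + len[k]
            }
          }
          pieces[[2L * length(pos) + 1L]] <- if (prev <= n)
            rr[prev:n] else raw(0)
          ev$indel <- do.call(rbind, rows)
          rr <- unlist(pieces, use.names = FALSE)
        }
      }
    }

    events <- if (length(ev) > 0) do.call(rbind, ev) else
      data.frame(type = character(0), pos = integer(0),
                 ref = character(0), alt = character(0),
                 stringsAsFactors = FALSE)
    rownames(events) <- NULL
    list(mutant = rawToChar(rr), events = events)
  })
}

#' Replay a mutation event log
#'
#' Independent (string-based) application of an event log produced by
#' [mutate()]: substitutions and N-runs first (in-place), then indels from
#' the highest reference position down. Serves as the replay oracle for the
#' simulator.
#'
#' @param reference the original reference sequence.
#' @param events the event log data.frame from [mutate()].
#' @return the reconstructed mutant (character scalar).
#' @export
apply_events <- function(reference, events) {
  v <- strsplit(reference, "", fixed = TRUE)[[1]]
  inplace <- events[events$type %in% c("snp", "nrun"), , drop = FALSE]
  for (k in seq_len(nrow(inplace))) {
    alt <- strsplit(inplace$alt[k], "", fixed = TRUE)[[1]]
    v[seq(inplace$pos[k], length.out = length(alt))] <- alt
  }
  indel <- events[events$type %in% c("ins", "del"), , drop = FALSE]
  indel <- indel[order(indel$pos), , drop = FALSE]
  pieces <- vector("list", 2L * nrow(indel) + 1L)
  prev <- 1L
  for (k in seq_len(nrow(indel))) {
    p <- indel$pos[k]
    pieces[[2L * k - 1L]] <- if (p > prev) v[prev:(p - 1L)] else character(0)
    if (indel$type[k] == "ins") {
      pieces[[2L * k]] <- strsplit(indel$alt[k], "", fixed = TRUE)[[1]]
      prev <- p
    } else {
      pieces[[2L * k]] <- character(0)
      prev <- p + nchar(indel$ref[k])
    }
  }
  pieces[[length(pieces)]] <- if (prev <= length(v)) v[prev:length(v)]
    else character(0)
  paste(unlist(pieces, use.names = FALSE), collapse = "")
}

#' Write a synthetic cohort to disk
#'
#' Writes the reference and `n_individuals` mutants (each drawn with an
#' independent sub-seed derived from `seed`) as FASTA files plus a JSON
#' manifest recording every per-individual seed and the model, so any
#' member can be regenerated independently.
#'
#' @param reference the reference sequence (character scalar).
#' @param n_individuals number of mutants to generate.
#' @param model a [mutation_model()] (its `seed` is replaced per
#'   individual).
#' @param out_dir output directory (created if missing).
#' @param seed master seed for the per-individual sub-seeds.
#' @return invisibly, the manifest list.
#' @export
make_cohort <- function(reference, n_individuals, model = mutation_model(),
                        out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sub_seeds <- if (n_individuals > 0)
    with_seed(seed, sample.int(.Machine$integer.max - 1L, n_individuals))
  else integer(0)
  write_fasta(c(reference = reference), file.path(out_dir, "reference.fa"))
  files <- character(n_individuals)
  for (i in seq_len(n_individuals)) {
    mi <- model
    mi$seed <- sub_seeds[i]
    res <- mutate(reference, mi)
    files[i] <- file.path(out_dir, sprintf("individual_%03d.fa", i))
    write_fasta(setNames(res$mutant, sprintf("individual_%03d", i)),
                files[i])
  }
  manifest <- list(
    n_individuals = n_individuals, master_seed = seed,
    model = unclass(model)[c("snp_rate", "indel_rate", "indel_mean",
                             "n_run_rate", "n_run_mean")],
    individuals = if (n_individuals > 0)
      data.frame(file = basename(files), seed = sub_seeds) else list())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
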