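#' @keywords internal
junction_key <- function(chrom, start, end) {
  paste0(chrom, ":", start, "-", end)
}

#' Canonical junctions of a reference isoform
#'
#' One junction per adjacent exon pair of the model, keyed by the genomic
#' intron interval (first and last intronic base, 1-based inclusive).
#'
#' @param model A [gene_model()].
#' @return Data frame with columns `intron` (index `i` for the intron
#'   between exons `i` and `i+1` in transcript order), `chrom`, `start`,
#'   `end`, `key`. Zero rows for a single-exon model.
#' @export
canonical_junctions <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  ex <- model$exons
  n <- nrow(ex)
  if (n < 2L) {
    return(data.frame(intron = integer(), chrom = character(),
                      start = integer(), end = integer(), key = character()))
  }
  i <- seq_len(n - 1L)
  if (model$strand == "+") {
    s <- ex$end[i] + 1L
    e <- ex$start[i + 1L] - 1L
  } else {
    s <- ex$end[i + 1L] + 1L
    e <- ex$start[i] - 1L
  }
  data.frame(intron = i, chrom = model$chrom, start = s, end = e,
             key = junction_key(model$chrom, s, e))
}

# empty splice-event data frame (schema shared by all constructors)
.empty_events <- function() {
  data.frame(gene = character(), name = character(), type = character(),
             skipped_exons = character(), target_exon = integer(),
             inserted_length = integer(), deleted_length = integer(),
             frame = character(), chrom = character(),
             span_start = integer(), span_end = integer(),
             strand = character(), supporting = character(),
             denominator = character(), stringsAsFactors = FALSE)
}

.frame_status <- function(inserted, deleted) {
  if ((inserted - deleted) %% 3 == 0) "in-frame" else "frameshift"
}

.event_row <- function(model, type, skipped, target_exon, inserted, deleted,
                       span, supporting, denominator) {
  data.frame(
    gene = model$gene, name = NA_character_, type = type,
    skipped_exons = if (length(skipped)) paste(skipped, collapse = ",") else "",
    target_exon = if (is.null(target_exon)) NA_integer_ else as.integer(target_exon),
    inserted_length = as.integer(inserted), deleted_length = as.integer(deleted),
    frame = .frame_status(inserted, deleted),
    chrom = model$chrom, span_start = as.integer(span[1]),
    span_end = as.integer(span[2]), strand = model$strand,
    supporting = paste(supporting, collapse = ","),
    denominator = paste(denominator, collapse = ","),
    stringsAsFactors = FALSE
  )
}

# classify one junction intron [a, b] against the model.
# Returns list(status = "canonical" | "event" | "ic_candidate" | "unassigned",
#              event = one-row data frame (event / ic_candidate), reason).
.classify_span <- function(model, a, b) {
  ex <- model$exons
  cj <- canonical_junctions(model)
  anchorL <- match(a - 1L, ex$end)    # exon ending immediately left of intron
  anchorR <- match(b + 1L, ex$start)  # exon starting immediately right
  if (model$strand == "+") {
    up <- anchorL; down <- anchorR
  } else {
    up <- anchorR; down <- anchorL
  }
  denom <- cj[cj$start <= b & cj$end >= a, , drop = FALSE]

  # deleted exonic bases under this junction and their transcript extent
  ov_lo <- pmax(ex$start, a)
  ov_hi <- pmin(ex$end, b)
  ov_w <- pmax(0L, ov_hi - ov_lo + 1L)
  del_len <- sum(ov_w)
  hit <- which(ov_w > 0L)

  if (!is.na(up) && !is.na(down)) {
    if (down == up + 1L) {
      return(list(status = "canonical", event = NULL, reason = NA_character_))
    }
    if (down <= up) {
      return(list(status = "unassigned", event = NULL,
                  reason = "anchors not colinear with transcript"))
    }
    skipped <- (up + 1L):(down - 1L)
    ev <- .event_row(model, "ESF", skipped,
                     target_exon = if (length(skipped) == 1L) skipped else NA,
                     inserted = 0L, deleted = del_len,
                     span = c(a, b), supporting = junction_key(model$chrom, a, b),
                     denominator = denom$key)
    return(list(status = "event", event = ev, reason = NA_character_))
  }

  if (xor(is.na(anchorL), is.na(anchorR))) {
    if (!is.na(anchorL)) {
      far_exon <- .exon_index_at(model, b + 1L)
      interior <- !is.na(far_exon) && ex$start[far_exon] != b + 1L
    } else {
      far_exon <- .exon_index_at(model, a - 1L)
      interior <- !is.na(far_exon) && ex$end[far_exon] != a - 1L
    }
    if (interior) {
      # partial exon skipping: one canonical anchor, far end strictly inside
      # an exon; deleted bases = truncated exon portion (+ any exons fully
      # spanned in between)
      full <- hit[ov_w[hit] == ex$width[hit]]
      ev <- .event_row(model, "ESP", full, target_exon = far_exon,
                       inserted = 0L, deleted = del_len,
                       span = c(a, b),
                       supporting = junction_key(model$chrom, a, b),
                       denominator = denom$key)
      return(list(status = "event", event = ev, reason = NA_character_))
    }
    # far end inside an intron: retention of the remainder of the host
    # intron (IP), or one side of a cryptic exon (IC) -- decided by pairing
    if (!is.na(anchorL)) {
      host <- which(cj$start == a & cj$end > b)
      if (length(host) == 1L && del_len == 0L) {
        ins <- c(b + 1L, cj$end[host])
        cand <- data.frame(a = a, b = b, host_intron = cj$intron[host],
                           side = "start", ins_lo = ins[1], ins_hi = ins[2],
                           key = junction_key(model$chrom, a, b))
        return(list(status = "ic_candidate", event = cand,
                    reason = NA_character_))
      }
    } else {
      host <- which(cj$end == b & cj$start < a)
      if (length(host) == 1L && del_len == 0L) {
        ins <- c(cj$start[host], a - 1L)
        cand <- data.frame(a = a, b = b, host_intron = cj$intron[host],
                           side = "end", ins_lo = ins[1], ins_hi = ins[2],
                           key = junction_key(model$chrom, a, b))
        return(list(status = "ic_candidate", event = cand,
                    reason = NA_character_))
      }
    }
    return(list(status = "unassigned", event = NULL,
                reason = "single anchor without interpretable far end"))
  }
  list(status = "unassigned", event = NULL, reason = "no canonical anchor")
}

# turn an unconsumed intronic candidate into a partial intron retention event
.ip_event <- function(model, cand) {
  ins_len <- cand$ins_hi - cand$ins_lo + 1L
  cj <- canonical_junctions(model)
  host_key <- cj$key[cj$intron == cand$host_intron]
  .event_row(model, "IP", integer(), target_exon = NA,
             inserted = ins_len, deleted = 0L,
             span = c(cand$ins_lo, cand$ins_hi),
             supporting = cand$key, denominator = host_key)
}

#' Classify one junction against a gene model
#'
#' Decides whether a junction is canonical, an exon-skipping or
#' intron-retention event, or unassigned. Junctions that could be one half
#' of a cryptic-exon pair are reported as partial intronic insertions (IP)
#' here; [detect_events()] upgrades compatible pairs to IC events.
#'
#' @param junction One-row data frame (or list) with `chrom`,
#'   `intron_start`, `intron_end`, `strand`.
#' @param model A [gene_model()].
#' @return List with `status` (`"canonical"`, `"event"` or `"unassigned"`),
#'   `event` (one-row event data frame or `NULL`) and `reason`.
#' @export
classify_junction <- function(junction, model) {
  stopifnot(inherits(model, "gene_model"))
  if (!identical(as.character(junction$chrom), model$chrom)) {
    return(list(status = "unassigned", event = NULL, reason = "wrong chromosome"))
  }
  s <- as.character(junction$strand)
  if (!s %in% c("*", model$strand)) {
    return(list(status = "unassigned", event = NULL, reason = "wrong strand"))
  }
  res <- .classify_span(model, as.integer(junction$intron_start),
                        as.integer(junction$intron_end))
  if (res$status == "ic_candidate") {
    ev <- .ip_event(model, res$event)
    ev$name <- name_event(ev, model)
    return(list(status = "event", event = ev, reason = NA_character_))
  }
  if (res$status == "event") res$event$name <- name_event(res$event, model)
  res
}

#' Pair intron-internal junctions into cryptic-exon (IC) events
#'
#' A junction running from a canonical donor to a point inside an intron,
#' together with a junction from a later point of the same intron to the
#' canonical acceptor, implies inclusion of the intervening intronic
#' segment as a cryptic exon. Pairing is greedy in coordinate order; each
#' junction joins at most one IC event, and pairs implying an empty segment
#' are rejected.
#'
#' @param candidates Data frame of candidates as produced internally by
#'   [detect_events()] (columns `a`, `b`, `host_intron`, `side`, `key`).
#' @param model A [gene_model()].
#' @return List with `events` (IC event rows) and `used` (keys of consumed
#'   candidate junctions).
#' @export
pair_cryptic_exons <- function(candidates, model) {
  events <- .empty_events()
  used <- character()
  if (is.null(candidates) || !nrow(candidates)) {
    return(list(events = events, used = used))
  }
  cj <- canonical_junctions(model)
  for (h in sort(unique(candidates$host_intron))) {
    left <- candidates[candidates$host_intron == h & candidates$side == "start", , drop = FALSE]
    right <- candidates[candidates$host_intron == h & candidates$side == "end", , drop = FALSE]
    left <- left[order(left$b), , drop = FALSE]
    right <- right[order(right$a), , drop = FALSE]
    taken <- rep(FALSE, nrow(right))
    for (i in seq_len(nrow(left))) {
      ok <- which(!taken & right$a >= left$b[i] + 2L)
      if (!length(ok)) next
      j <- ok[1]
      taken[j] <- TRUE
      exon_lo <- left$b[i] + 1L
      exon_hi <- right$a[j] - 1L
      ev <- .event_row(model, "IC", integer(), target_exon = NA,
                       inserted = exon_hi - exon_lo + 1L, deleted = 0L,
                       span = c(exon_lo, exon_hi),
                       supporting = c(left$key[i], right$key[j]),
                       denominator = cj$key[cj$intron == h])
      events <- rbind(events, ev)
      used <- c(used, left$key[i], right$key[j])
    }
  }
  list(events = events, used = used)
}

#' Deterministic r.-style event name
#'
#' Deletions (full or partial exon skipping) are named
#' `r.<first>_<last>del` over the deleted transcript positions. Insertions
#' (intron retention and cryptic exons) are named
#' `r.<left>_<right>ins<start>_<end>`, where the insertion point is the
#' canonical exon boundary and the inserted intronic bases carry
#' nearest-boundary offset labels from [genomic_to_transcript()]. The same
#' event always yields the same string.
#'
#' @param event One-row event data frame.
#' @param model The [gene_model()] the event belongs to.
#' @return Character name.
#' @export
name_event <- function(event, model) {
  stopifnot(inherits(model, "gene_model"), nrow(event) == 1L)
  ex <- model$exons
  if (length(model$excluded_exons)) {
    affected <- .affected_exons(event, model)
    if (length(intersect(affected, model$excluded_exons))) {
      stop("event in gene ", model$gene,
           " spans excluded exons and should have been filtered")
    }
  }
  if (event$type %in% c("ESF", "ESP", "ES")) {
    # transcript extent of the deleted exonic bases
    lo <- event$span_start; hi <- event$span_end
    dlo <- pmax(ex$start, lo); dhi <- pmin(ex$end, hi)
    keep <- which(dhi >= dlo)
    tpos <- unlist(lapply(keep, function(k) {
      c(.tx_position(model, dlo[k]), .tx_position(model, dhi[k]))
    }))
    sprintf("r.%d_%ddel", min(tpos), max(tpos))
  } else if (event$type %in% c("IP", "IC")) {
    cj <- canonical_junctions(model)
    host <- cj[cj$key == strsplit(event$denominator, ",")[[1]][1], ]
    u <- ex$tx_end[host$intron]
    g <- c(event$span_start, event$span_end)
    if (model$strand == "-") g <- rev(g)  # transcript orientation
    labs <- genomic_to_transcript(model, g)
    sprintf("r.%d_%dins%s_%s", u, u + 1L, labs[1], labs[2])
  } else {
    stop("unknown event type: ", event$type)
  }
}

# exon indices an event touches (skipped/truncated exons plus the exons
# flanking each canonical junction it replaces); used for exclusion filtering
.affected_exons <- function(event, model) {
  sk <- if (nzchar(event$skipped_exons)) {
    as.integer(strsplit(event$skipped_exons, ",")[[1]])
  } else integer()
  tgt <- if (!is.na(event$target_exon)) event$target_exon else integer()
  cj <- canonical_junctions(model)
  dk <- strsplit(event$denominator, ",")[[1]]
  introns <- cj$intron[cj$key %in% dk]
  sort(unique(c(sk, tgt, introns, introns + 1L)))
}

#' Detect splicing events of one gene in one sample
#'
#' Compares a sample's junction records with the gene's reference isoform
#' and returns the classified non-canonical events: full/partial exon
#' skipping (ESF/ESP), partial intronic insertion (IP) and cryptic exon
#' (IC). Intron-internal junction pairs are first combined into IC events;
#' leftovers become IP. Events touching the model's excluded exons are
#' dropped.
#'
#' @param model A [gene_model()].
#' @param junctions Data frame from [read_junctions()].
#' @param min_unique Minimum unique read support for a junction to be
#'   considered (default 1; unsupported junctions are treated as absent).
#' @return Event data frame (one row per event, named); attribute
#'   `unassigned` carries the junctions that matched no pattern with a
#'   reason each.
#' @export
detect_events <- function(model, junctions, min_unique = 1L) {
  stopifnot(inherits(model, "gene_model"))
  ex <- model$exons
  span <- c(min(ex$start), max(ex$end))
  j <- junctions[junctions$chrom == model$chrom &
                   junctions$unique_reads >= min_unique &
                   junctions$intron_start <= span[2] &
                   junctions$intron_end >= span[1], , drop = FALSE]
  events <- .empty_events()
  cands <- NULL
  unassigned <- data.frame(key = character(), reason = character())
  if (nrow(j)) {
    j <- j[!duplicated(junction_key(j$chrom, j$intron_start, j$intron_end)), ,
           drop = FALSE]
    for (i in seq_len(nrow(j))) {
      s <- as.character(j$strand[i])
      if (!s %in% c("*", model$strand)) {
        unassigned <- rbind(unassigned, data.frame(
          key = junction_key(j$chrom[i], j$intron_start[i], j$intron_end[i]),
          reason = "wrong strand"))
        next
      }
      res <- .classify_span(model, j$intron_start[i], j$intron_end[i])
      if (res$status == "event") {
        events <- rbind(events, res$event)
      } else if (res$status == "ic_candidate") {
        cands <- rbind(cands, res$event)
      } else if (res$status == "unassigned") {
        unassigned <- rbind(unassigned, data.frame(
          key = junction_key(j$chrom[i], j$intron_start[i], j$intron_end[i]),
          reason = res$reason))
      }
    }
  }
  paired <- pair_cryptic_exons(cands, model)
  events <- rbind(events, paired$events)
  if (!is.null(cands) && nrow(cands)) {
    left_over <- cands[!cands$key %in% paired$used, , drop = FALSE]
    for (i in seq_len(nrow(left_over))) {
      events <- rbind(events, .ip_event(model, left_over[i, ]))
    }
  }
  if (nrow(events)) {
    if (length(model$excluded_exons)) {
      keep <- vapply(seq_len(nrow(events)), function(i) {
        !length(intersect(.affected_exons(events[i, ], model),
                          model$excluded_exons))
      }, logical(1))
      events <- events[keep, , drop = FALSE]
    }
    if (nrow(events)) {
      events$name <- vapply(seq_len(nrow(events)), function(i) {
        name_event(events[i, ], model)
      }, character(1))
      events <- events[order(events$span_start, events$span_end, events$type), ,
                       drop = FALSE]
      rownames(events) <- NULL
    }
  }
  attr(events, "unassigned") <- unassigned
  events
}

#' Build the event catalog across samples
#'
#' Unions the events detected in every sample into one catalog (unique by
#' gene and name), so each event can then be quantified in all samples,
#' including samples where it has zero supporting reads.
#'
#' @param models Named list of [gene_model()] objects.
#' @param junction_sets Named list (one element per sample) of junction
#'   data frames.
#' @param min_unique Passed to [detect_events()].
#' @return Event data frame (catalog).
#' @export
build_event_catalog <- function(models, junction_sets, min_unique = 1L) {
  all_ev <- .empty_events()
  for (jx in junction_sets) {
    for (m in models) {
      ev <- detect_events(m, jx, min_unique = min_unique)
      if (nrow(ev)) all_ev <- rbind(all_ev, ev)
    }
  }
  all_ev <- all_ev[!duplicated(paste(all_ev$gene, all_ev$name)), , drop = FALSE]
  all_ev <- all_ev[order(all_ev$gene, all_ev$span_start, all_ev$name), ,
                   drop = FALSE]
  rownames(all_ev) <- NULL
  all_ev
}

#' Aggregate full and partial skipping of the same exon (ES)
#'
#' For reporting, full (ESF) and partial (ESP) skipping events targeting
#' the same exon are combined into one exon-skipping (ES) aggregate; the
#' component events keep their identity.
#'
#' @param events Event data frame.
#' @return Data frame with one row per (gene, exon) that has at least one
#'   skipping component: columns `gene`, `target_exon`, `type` (`"ES"`),
#'   `n_components`, `components` (comma-separated component names).
#' @export
merge_es <- function(events) {
  comp <- events[events$type %in% c("ESF", "ESP") & !is.na(events$target_exon), ,
                 drop = FALSE]
  if (!nrow(comp)) {
    return(data.frame(gene = character(), target_exon = integer(),
                      type = character(), n_components = integer(),
                      components = character()))
  }
  key <- paste(comp$gene, comp$target_exon)
  out <- do.call(rbind, lapply(split(comp, key), function(d) {
    data.frame(gene = d$gene[1], target_exon = d$target_exon[1], type = "ES",
               n_components = nrow(d),
               components = paste(sort(d$name), collapse = ","))
  }))
  out <- out[order(out$gene, out$target_exon), , drop = FALSE]
  rownames(out) <- NULL
  out
}
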