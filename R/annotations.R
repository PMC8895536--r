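#' Read a chemical-protein annotation table
#'
#' Parses a tab-separated annotation file with columns
#' \code{chemical_id}, \code{target}, \code{mode}, \code{support}.
#' Mode is encoded as \code{+} (activation), \code{-} (inhibition) or
#' \code{unspecified}, mirroring reference chemical databases that record a
#' per-association literature support level.
#'
#' @param path Path to a TSV file with a header row.
#' @return A data frame with columns \code{chemical_id}, \code{target},
#'   \code{mode} (one of \code{"positive"}, \code{"negative"},
#'   \code{"unspecified"}) and integer \code{support}.
#' @export
read_annotations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("chemical_id", "target", "mode", "support")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("annotation file lacks column(s): ", paste(missing_cols, collapse = ", "))
  df$support <- suppressWarnings(as.integer(df$support))
  df$mode <- decode_mode(df$mode)
  validate_annotations(df[needed])
}

decode_mode <- function(x) {
  out <- rep(NA_character_, length(x))
  out[x %in% c("+", "positive")] <- "positive"
  out[x %in% c("-", "negative")] <- "negative"
  out[x == "unspecified"] <- "unspecified"
  out
}

validate_annotations <- function(records) {
  bad <- which(is.na(records$mode))
  if (length(bad))
    stop("unknown mode string in annotation row(s): ",
         paste(head(bad, 5L), collapse = ", "))
  if (any(is.na(records$support) | records$support < 1L))
    stop("support must be a positive integer for every annotation row")
  records
}

#' Compose an MIE label from a target and a mode
#'
#' @param target Gene symbol(s).
#' @param mode \code{"positive"} or \code{"negative"}.
#' @return Character label such as \code{"ESR1 (-)"}.
#' @export
mie_label <- function(target, mode) {
  sign <- ifelse(mode == "positive", "+", "-")
  paste0(target, " (", sign, ")")
}

#' Derive MIE-labeled records and resolve mode conflicts
#'
#' Drops \code{unspecified}-mode rows, collapses duplicate
#' (chemical, target, mode) rows to their maximum support, and resolves
#' chemical-target pairs annotated with both modes by keeping the record
#' with the strictly higher support level. An exact support tie between
#' opposing modes drops both records with a warning. Records below
#' \code{min_support} are retained but flagged (\code{high_support = FALSE});
#' moderate-support chemicals are needed later for rank-based validation.
#'
#' @param records Data frame as returned by [read_annotations()].
#' @param min_support Support level at and above which an annotation counts
#'   as high-confidence (default 5).
#' @return Data frame \code{chemical_id}, \code{target}, \code{mode},
#'   \code{label}, \code{support}, \code{high_support}, one row per
#'   surviving (chemical, target) pair.
#' @export
derive_mie_records <- function(records, min_support = 5L) {
  validate_annotations(records)
  if (min_support < 1L) stop("min_support must be >= 1")
  rec <- records[records$mode != "unspecified", , drop = FALSE]
  if (!nrow(rec)) {
    return(data.frame(chemical_id = character(), target = character(),
                      mode = character(), label = character(),
                      support = integer(), high_support = logical()))
  }
  # duplicates within one mode: keep max support
  key3 <- paste(rec$chemical_id, rec$target, rec$mode, sep = "\r")
  ord <- order(key3, -rec$support)
  rec <- rec[ord[!duplicated(key3[ord])], , drop = FALSE]
  # opposing-mode conflict per (chemical, target)
  key2 <- paste(rec$chemical_id, rec$target, sep = "\r")
  dup_keys <- unique(key2[duplicated(key2)])
  drop <- logical(nrow(rec))
  for (k in dup_keys) {
    idx <- which(key2 == k)
    s <- rec$support[idx]
    if (max(s) == min(s)) {
      warning("support tie between opposing modes for chemical '",
              rec$chemical_id[idx[1L]], "' and target '",
              rec$target[idx[1L]], "'; dropping both records")
      drop[idx] <- TRUE
    } else {
      drop[idx[s < max(s)]] <- TRUE
    }
  }
  rec <- rec[!drop, , drop = FALSE]
  out <- data.frame(chemical_id = rec$chemical_id, target = rec$target,
                    mode = rec$mode,
                    label = mie_label(rec$target, rec$mode),
                    support = rec$support,
                    high_support = rec$support >= min_support,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$chemical_id, out$target), , drop = FALSE]
}

#' Collect per-MIE chemical sets from derived records
#'
#' @param records Output of [derive_mie_records()].
#' @param high_support_only Keep only high-confidence chemicals in each MIE's
#'   chemical map (default TRUE; the similarity clustering and eligibility
#'   rules operate on high-confidence associations).
#' @return Data frame with one row per MIE label and list-columns
#'   \code{targets} and \code{chemicals} (named integer support vectors).
#' @export
collect_mies <- function(records, high_support_only = TRUE) {
  rec <- if (high_support_only)
    records[records$high_support, , drop = FALSE] else records
  if (!nrow(rec))
    return(data.frame(label = character(), mode = character()))
  labs <- sort(unique(rec$label))
  rows <- lapply(labs, function(l) {
    r <- rec[rec$label == l, , drop = FALSE]
    list(mode = r$mode[1L], targets = unique(r$target),
         chemicals = setNames(as.integer(r$support), r$chemical_id))
  })
  data.frame(label = labs,
             mode = vapply(rows, `[[`, "", "mode"),
             targets = I(lapply(rows, `[[`, "targets")),
             chemicals = I(lapply(rows, `[[`, "chemicals")),
             stringsAsFactors = FALSE)
}

#' Jaccard similarity of two chemical sets
#'
#' \eqn{J(A,B) = |A \cap B| / |A \cup B|}.
#'
#' @param set_a,set_b Character vectors (treated as sets).
#' @return Similarity in \[0, 1\].
#' @export
jaccard <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  u <- length(union(a, b))
  if (u == 0L) stop("jaccard undefined: both sets are empty")
  length(intersect(a, b)) / u
}

#' Merge similar MIEs by hierarchical clustering of chemical-set overlap
#'
#' Pairwise dissimilarity between MIEs is 1 minus the Jaccard index of their
#' chemical sets. MIEs are clustered within mode only (a target's activation
#' and inhibition are never merged) using hierarchical clustering and a tree
#' cut at \code{cut_height}.
#'
#' @param mies Data frame from [collect_mies()].
#' @param cut_height Tree cut height on the dissimilarity scale (default 0.7).
#' @param method Linkage passed to [stats::hclust()] (default
#'   \code{"complete"}).
#' @return Data frame with one row per cluster: \code{cluster_id},
#'   \code{display_name}, \code{mode}, list-columns \code{members},
#'   \code{targets} and \code{chemicals} (union of member chemical sets,
#'   support = max across members).
#' @export
cluster_mies <- function(mies, cut_height = 0.7, method = "complete") {
  if (!nrow(mies)) stop("at least one MIE is required")
  out <- list()
  next_id <- 1L
  for (mode in c("positive", "negative")) {
    sub <- mies[mies$mode == mode, , drop = FALSE]
    if (!nrow(sub)) next
    if (nrow(sub) == 1L) {
      grp <- setNames(1L, sub$label)
    } else {
      n <- nrow(sub)
      d <- matrix(0, n, n, dimnames = list(sub$label, sub$label))
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <-
          1 - jaccard(names(sub$chemicals[[i]]), names(sub$chemicals[[j]]))
      }
      grp <- cutree(hclust(stats::as.dist(d), method = method),
                    h = cut_height)
    }
    for (g in sort(unique(grp))) {
      members <- sub[grp == g, , drop = FALSE]
      chem <- combine_chemical_maps(members$chemicals)
      out[[length(out) + 1L]] <- data.frame(
        cluster_id = next_id,
        display_name = name_cluster(members$label),
        mode = mode,
        members = I(list(sort(members$label))),
        targets = I(list(sort(unique(unlist(members$targets))))),
        chemicals = I(list(chem)),
        stringsAsFactors = FALSE)
      next_id <- next_id + 1L
    }
  }
  do.call(rbind, out)
}

combine_chemical_maps <- function(maps) {
  all <- unlist(unname(maps))
  tapply_max <- tapply(all, names(all), max)
  setNames(as.integer(tapply_max), names(tapply_max))[sort(names(tapply_max))]
}

#' Deterministic display name for a cluster of MIE labels
#'
#' Gene families sharing a common symbol prefix collapse to
#' \code{prefix-suffix1/suffix2 (mode)} (e.g. \code{ESR1 (-)} and
#' \code{ESR2 (-)} become \code{"ESR-1/2 (-)"}); otherwise member symbols are
#' joined with \code{"/"}. Singletons pass through unchanged.
#'
#' @param members Character vector of MIE labels sharing one mode.
#' @return A display name string.
#' @export
name_cluster <- function(members) {
  if (!length(members)) stop("members must be nonempty")
  parsed <- parse_mie_labels(members)
  if (length(unique(parsed$mode)) != 1L)
    stop("cluster members mix modes: ", paste(members, collapse = ", "))
  genes <- sort(unique(parsed$target))
  sign <- if (parsed$mode[1L] == "positive") "+" else "-"
  if (length(genes) == 1L) return(paste0(genes, " (", sign, ")"))
  prefix <- common_prefix(genes)
  suffixes <- substring(genes, nchar(prefix) + 1L)
  name <- if (nzchar(prefix) && all(nzchar(suffixes)))
    paste0(prefix, "-", paste(suffixes, collapse = "/"))
  else
    paste(genes, collapse = "/")
  paste0(name, " (", sign, ")")
}

parse_mie_labels <- function(labels) {
  m <- regmatches(labels, regexec("^(.*) \\(([+-])\\)$", labels))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad)) stop("malformed MIE label(s): ",
                     paste(labels[bad], collapse = ", "))
  data.frame(target = vapply(m, `[`, "", 2L),
             mode = ifelse(vapply(m, `[`, "", 3L) == "+",
                           "positive", "negative"),
             stringsAsFactors = FALSE)
}

common_prefix <- function(x) {
  if (length(x) < 2L) return(x[1L])
  chars <- strsplit(x, "")
  n <- min(lengths(chars))
  k <- 0L
  while (k < n &&
         length(unique(vapply(chars, `[`, "", k + 1L))) == 1L) k <- k + 1L
  substr(x[1L], 1L, k)
}

#' Write a cluster table to TSV
#'
#' Columns: \code{cluster_id}, \code{display_name}, \code{member_labels}
#' (comma-joined), \code{chemical_ids} (comma-joined).
#'
#' @param clusters Output of [cluster_mies()].
#' @param path Output path.
#' @export
write_cluster_table <- function(clusters, path) {
  df <- data.frame(
    cluster_id = clusters$cluster_id,
    display_name = clusters$display_name,
    member_labels = vapply(clusters$members, paste, "", collapse = ","),
    chemical_ids = vapply(clusters$chemicals,
                          function(m) paste(names(m), collapse = ","), ""),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
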