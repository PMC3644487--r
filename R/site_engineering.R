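site_key <- function(df) paste(df$enzyme, df$start, df$strand)

empty_sites <- function() {
  data.frame(enzyme = character(0), start = integer(0), strand = character(0),
             width = integer(0), site = character(0), stringsAsFactors = FALSE)
}

# IUPAC pattern -> PCRE with character classes; cached, since the same few
# recognition patterns are matched thousands of times during site
# engineering
.regex_cache <- new.env(parent = emptyenv())
iupac_to_regex <- function(pattern) {
  hit <- .regex_cache[[pattern]]
  if (!is.null(hit)) return(hit)
  sym <- strsplit(pattern, "")[[1]]
  bad <- setdiff(unique(sym), IUPAC_SYMBOLS)
  if (length(bad))
    stop("illegal IUPAC symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
  parts <- vapply(sym, function(s) {
    exp <- Biostrings::IUPAC_CODE_MAP[[s]]
    if (nchar(exp) == 1L) exp else paste0("[", exp, "]")
  }, "")
  rx <- paste0("(?=", paste(parts, collapse = ""), ")")
  assign(pattern, rx, envir = .regex_cache)
  rx
}

match_starts <- function(pattern, subject) {
  # all (overlapping) 1-based start positions of an IUPAC pattern in a
  # concrete ACGT subject; lookahead regex so overlapping hits are reported
  if (nchar(pattern) > nchar(subject)) return(integer(0))
  st <- gregexpr(iupac_to_regex(pattern), subject, perl = TRUE)[[1]]
  if (st[[1]] == -1L) integer(0) else as.integer(st)
}

# raw site scan over the enabled enzymes of a catalog data frame: parallel
# vectors, no data-frame overhead (the engineering loops call this
# thousands of times)
scan_sites <- function(seq, enz) {
  enzyme <- character(0); start <- integer(0); strand <- character(0)
  width <- integer(0)
  for (i in seq_len(nrow(enz))) {
    pat <- enz$recognition[[i]]
    fwd <- match_starts(pat, seq)
    if (length(fwd)) {
      enzyme <- c(enzyme, rep(enz$name[[i]], length(fwd)))
      start <- c(start, fwd)
      strand <- c(strand, rep("+", length(fwd)))
      width <- c(width, rep(nchar(pat), length(fwd)))
    }
    if (!enz$palindromic[[i]]) {
      rc <- match_starts(enz$rc[[i]], seq)
      if (length(rc)) {
        enzyme <- c(enzyme, rep(enz$name[[i]], length(rc)))
        start <- c(start, rc)
        strand <- c(strand, rep("-", length(rc)))
        width <- c(width, rep(nchar(pat), length(rc)))
      }
    }
  }
  list(enzyme = enzyme, start = start, strand = strand, width = width)
}

scan_keys <- function(seq, enz) {
  s <- scan_sites(seq, enz)
  if (!length(s$start)) character(0) else paste(s$enzyme, s$start, s$strand)
}

#' Find restriction sites in a sequence
#'
#' Reports every position at which an enabled enzyme's (possibly
#' degenerate) recognition pattern matches, including overlapping matches.
#' Palindromic patterns are reported once with strand `+`; non-palindromic
#' patterns are additionally searched as their reverse complement and those
#' matches reported with strand `-`.  Start positions are 1-based and refer
#' to the first base of the recognition site within `seq`.
#'
#' @param seq DNA string over `ACGT`.
#' @param catalog an `enzyme_catalog`; only enabled enzymes are searched.
#' @return data frame with columns `enzyme`, `start`, `strand`, `width`,
#'   `site` (the matched bases of `seq`), ordered by position then enzyme.
#' @export
find_sites <- function(seq, catalog) {
  seq <- normalize_dna(as.character(seq))
  s <- scan_sites(seq, enabled_enzymes(catalog))
  if (!length(s$start)) return(empty_sites())
  out <- data.frame(enzyme = s$enzyme, start = s$start, strand = s$strand,
                    width = s$width,
                    site = substring(seq, s$start, s$start + s$width - 1L),
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$enzyme, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# codon indices (1-based within a window) spanned by site positions
spanned_codons <- function(start, width) {
  ((start - 1L) %/% 3L + 1L):((start + width - 2L) %/% 3L + 1L)
}

# allowed codon set for window codon k of a candidate: synonymous codons of
# the candidate's residue, or the forced codon for a forced mutated position
allowed_codons <- function(window, candidate, k) {
  for (sp in window$specs) {
    if (sp$aa_position - window$first_codon + 1L == k &&
        !is.null(sp$forced_codon))
      return(sp$forced_codon)
  }
  synonymous_codons(substr(candidate$residues, k, k))
}

replace_codons <- function(bases, idx, codons) {
  for (j in seq_along(idx)) {
    k <- idx[[j]]
    substr(bases, 3L * k - 2L, 3L * k) <- codons[[j]]
  }
  bases
}

#' Silently remove restriction sites from a candidate window
#'
#' Re-assigns synonymous codons over the codons spanned by the matched
#' site(s) so that no site of the matched enzymes remains anywhere in the
#' window, using the minimum number of nucleotide changes.  Overlapping
#' matches are eliminated jointly.  Ties on the number of changes are
#' broken by GC content closest to `gc_target`, then lexicographically.
#' Only codons overlapping a matched site are ever edited; translation is
#' preserved exactly.
#'
#' @param window a `mutation_window`.
#' @param candidate an `sdm_candidate` built on that window.
#' @param matches data frame of sites to destroy (rows of
#'   [find_sites()] on `candidate$bases`); default: all enabled-enzyme
#'   sites found in the candidate.
#' @param catalog an `enzyme_catalog`.
#' @param protect_other_sites refuse edits that create a new site of any
#'   enabled enzyme elsewhere in the window (default TRUE).
#' @param gc_target GC percentage targeted by the tie-break (default 50).
#' @return a list: `status` (`"ok"`, `"no_sites"` or `"unremovable"`),
#'   `candidate` (the edited `sdm_candidate`, origin `"removal"`; unchanged
#'   input when there was nothing to remove), `removed` (the match rows),
#'   and `edit` (positions changed relative to the input candidate,
#'   `before`/`after` strings, `n_changes`, `gc_after`).
#' @export
remove_sites_silently <- function(window, candidate, matches = NULL,
                                  catalog, protect_other_sites = TRUE,
                                  gc_target = 50) {
  stopifnot(inherits(window, "mutation_window"),
            inherits(candidate, "sdm_candidate"))
  if (is.null(matches)) matches <- find_sites(candidate$bases, catalog)
  if (!nrow(matches))
    return(list(status = "no_sites", candidate = candidate,
                removed = matches, edit = NULL))
  target_enzymes <- unique(matches$enzyme)
  target_cat <- select_enzymes(catalog, intersect(attr(catalog, "selection"),
                                                  target_enzymes))
  idx <- sort(unique(unlist(Map(spanned_codons, matches$start, matches$width))))
  n_codons <- nchar(candidate$bases) %/% 3L
  idx <- idx[idx >= 1L & idx <= n_codons]
  sets <- lapply(idx, function(k) allowed_codons(window, candidate, k))
  if (prod(vapply(sets, length, 1L)) > 250000L)
    stop("site removal search space too large (", length(idx),
         " codons spanned)", call. = FALSE)
  grid <- expand.grid(rev(sets), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)[, rev(seq_along(sets)), drop = FALSE]
  enz_all <- enabled_enzymes(catalog)
  enz_target <- enabled_enzymes(target_cat)
  before_keys <- scan_keys(candidate$bases, enz_all)
  cand_chars <- strsplit(candidate$bases, "")[[1]]
  best <- NULL
  for (r in seq_len(nrow(grid))) {
    newb <- replace_codons(candidate$bases, idx, as.character(grid[r, ]))
    if (length(scan_keys(newb, enz_target))) next
    if (protect_other_sites) {
      keys <- scan_keys(newb, enz_all)
      if (length(setdiff(keys, before_keys))) next
    }
    nch <- sum(strsplit(newb, "")[[1]] != cand_chars)
    gcd <- abs(gc_percent(newb) - gc_target)
    cand_rank <- list(n = nch, gcd = gcd, bases = newb)
    if (is.null(best) ||
        nch < best$n ||
        (nch == best$n && gcd < best$gcd - 1e-9) ||
        (nch == best$n && abs(gcd - best$gcd) <= 1e-9 && newb < best$bases))
      best <- cand_rank
  }
  if (is.null(best))
    return(list(status = "unremovable", candidate = candidate,
                removed = matches, edit = NULL))
  out <- new_candidate(window, best$bases, origin = "removal")
  changed <- which(strsplit(best$bases, "")[[1]] != cand_chars)
  list(status = "ok", candidate = out, removed = matches,
       edit = list(positions = changed, before = candidate$bases,
                   after = best$bases, n_changes = length(changed),
                   gc_after = gc_percent(best$bases)))
}

#' Codon-context realizations of a recognition site at a frame offset
#'
#' A recognition site placed at frame offset `offset` (0, 1 or 2 bases into
#' a codon) partially covers its first and last codons; completing those
#' partial codons with every possible base yields the full set of
#' codon-aligned nucleotide stretches that contain the site.  For a
#' non-degenerate 6-nt site split across codons as `NN/NNN/N` the set has
#' exactly 64 members.
#'
#' @param recognition IUPAC recognition pattern.
#' @param offset 0, 1 or 2: offset of the site's first base within its
#'   first codon.
#' @return character vector of codon-aligned stretches (length a multiple
#'   of 3) each containing the site at position `offset + 1`.
#' @export
site_frame_realizations <- function(recognition, offset) {
  offset <- as.integer(offset)
  stopifnot(offset %in% 0:2)
  L <- nchar(recognition)
  lead <- strrep("N", offset)
  trail <- strrep("N", (3L - (offset + L) %% 3L) %% 3L)
  expand_iupac(paste0(lead, recognition, trail))
}

#' Silently insert restriction sites into a candidate window
#'
#' Scans every window offset and every concrete realization of each enabled
#' enzyme's recognition pattern; codons partially covered by the site are
#' completed with every base combination consistent with the window's
#' (mutated) residue string, so each emitted candidate preserves the
#' translation exactly.  This realizes the recognition site as nucleotides
#' at the exact location while keeping the amino-acid sequence intact.
#' Non-palindromic patterns are also placed in reverse-complement
#' orientation and annotated with strand `-`.
#'
#' @param window a `mutation_window`.
#' @param candidate an `sdm_candidate`.
#' @param catalog an `enzyme_catalog`.
#' @param max_expansion skip patterns with more concrete realizations than
#'   this (default 256), with a warning.
#' @param unique_only drop insertions whose edits also create another new
#'   enabled-enzyme site in the window, so the identifier stays unique
#'   (default TRUE).
#' @param both_strands also place non-palindromic sites in `-` orientation
#'   (default TRUE).
#' @return list of results, each a list with `candidate` (origin
#'   `"insertion"`) and `site` (a one-row [find_sites()]-style data frame
#'   for the created site).  Empty list when no insertion is possible.
#' @export
insert_sites_silently <- function(window, candidate, catalog,
                                  max_expansion = 256L, unique_only = TRUE,
                                  both_strands = TRUE) {
  stopifnot(inherits(window, "mutation_window"),
            inherits(candidate, "sdm_candidate"))
  enz <- enabled_enzymes(catalog)
  n <- nchar(candidate$bases)
  n_codons <- n %/% 3L
  existing_keys <- scan_keys(candidate$bases, enz)
  allowed_all <- lapply(seq_len(n_codons), function(k)
    allowed_codons(window, candidate, k))
  # 3 x n character matrix per codon set, for vectorized base filtering
  allowed_mats <- lapply(allowed_all, function(s)
    matrix(unlist(strsplit(s, ""), use.names = FALSE), nrow = 3L))
  out <- list()
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(enz))) {
    pat <- enz$recognition[[i]]
    if (iupac_cardinality(pat) > max_expansion) {
      warning(sprintf(
        "skipping %s for insertion: %d realizations exceed the cap of %d",
        enz$name[[i]], iupac_cardinality(pat), max_expansion), call. = FALSE)
      next
    }
    L <- nchar(pat)
    if (L > 3L * n_codons) next
    orientations <- list(c("+", pat))
    if (both_strands && !enz$palindromic[[i]])
      orientations <- c(orientations, list(c("-", enz$rc[[i]])))
    for (ori in orientations) {
      strand <- ori[[1]]
      reals <- expand_iupac(ori[[2]])
      for (p in seq_len(3L * n_codons - L + 1L)) {
        idx <- spanned_codons(p, L)
        sets0 <- allowed_all[idx]
        rchars <- strsplit(reals, "")
        for (ri in seq_along(reals)) {
          r <- reals[[ri]]
          # restrict each spanned codon to codons matching the realization
          # over the overlapped bases
          sets <- sets0
          ok <- TRUE
          for (j in seq_along(idx)) {
            k <- idx[[j]]
            cod_start <- 3L * k - 2L
            ov <- max(p, cod_start):min(p + L - 1L, cod_start + 2L)
            need <- rchars[[ri]][ov - p + 1L]
            mat <- allowed_mats[[k]][ov - cod_start + 1L, , drop = FALSE]
            keep <- colSums(mat != need) == 0L
            if (!any(keep)) { ok <- FALSE; break }
            sets[[j]] <- sets[[j]][keep]
          }
          if (!ok) next
          grid <- expand.grid(rev(sets), KEEP.OUT.ATTRS = FALSE,
                              stringsAsFactors = FALSE)[, rev(seq_along(sets)),
                                                        drop = FALSE]
          for (rr in seq_len(nrow(grid))) {
            newb <- replace_codons(candidate$bases, idx,
                                   as.character(grid[rr, ]))
            key <- paste(newb, enz$name[[i]], p, strand)
            if (!is.null(seen[[key]])) next
            seen[[key]] <- TRUE
            keys_new <- scan_keys(newb, enz)
            this_key <- paste(enz$name[[i]], p, strand)
            if (!this_key %in% keys_new) next  # self-destroyed
            if (unique_only &&
                length(setdiff(keys_new, c(existing_keys, this_key)))) next
            site <- data.frame(enzyme = enz$name[[i]], start = p,
                               strand = strand, width = L,
                               site = substr(newb, p, p + L - 1L),
                               stringsAsFactors = FALSE)
            out[[length(out) + 1L]] <- list(
              candidate = new_candidate(window, newb, origin = "insertion"),
              site = site)
          }
        }
      }
    }
  }
  out
}

# attach gained/lost annotations (vs the wild-type window) to a candidate
annotate_sites <- function(candidate, window, catalog,
                           wt_sites = find_sites(window$wt_bases, catalog)) {
  cand_sites <- find_sites(candidate$bases, catalog)
  candidate$sites_gained <-
    cand_sites[!site_key(cand_sites) %in% site_key(wt_sites), , drop = FALSE]
  candidate$sites_lost <-
    wt_sites[!site_key(wt_sites) %in% site_key(cand_sites), , drop = FALSE]
  candidate
}

fmt_sites <- function(df) {
  if (is.null(df) || !nrow(df)) return("")
  paste(sprintf("%s @%d%s", df$enzyme, df$start,
                ifelse(df$strand == "-", "(-)", "")), collapse = "; ")
}

#' Survey all identifier-bearing candidates for a window
#'
#' Pools the plain substitution candidates, their silent-removal variants
#' (for candidates carrying enabled-enzyme sites) and all silent-insertion
#' variants, de-duplicated by base string and annotated with sites gained
#' and lost relative to the wild-type window.
#'
#' @inheritParams insert_sites_silently
#' @param cap candidate cap forwarded to [enumerate_candidates()].
#' @return list of annotated `sdm_candidate` objects.
#' @export
survey_candidates <- function(window, catalog, cap = 10000L,
                              max_expansion = 256L) {
  cands <- enumerate_candidates(window, cap = cap)
  wt_sites <- find_sites(window$wt_bases, catalog)
  pool <- cands
  for (cand in cands) {
    m <- find_sites(cand$bases, catalog)
    if (nrow(m)) {
      res <- remove_sites_silently(window, cand, m, catalog)
      if (res$status == "ok" && res$candidate$bases != cand$bases)
        pool[[length(pool) + 1L]] <- res$candidate
    }
    ins <- insert_sites_silently(window, cand, catalog,
                                 max_expansion = max_expansion)
    for (v in ins) pool[[length(pool) + 1L]] <- v$candidate
  }
  pool <- pool[!duplicated(vapply(pool, `[[`, "", "bases"))]
  lapply(pool, annotate_sites, window = window, catalog = catalog,
         wt_sites = wt_sites)
}

#' Rank candidate windows for primer design
#'
#' Deterministic pre-evaluation table of annotated candidates, sorted by
#' number of nucleotide changes (ascending), then GC distance from 50%,
#' then base string.  One row is selected (by the user or automatically)
#' for primer design.
#'
#' @param candidates list of annotated `sdm_candidate` objects (e.g. from
#'   [survey_candidates()]).
#' @return data frame with columns `candidate` (row number after sorting),
#'   `bases`, `residues`, `n_changes`, `changed`, `gc`, `sites_gained`,
#'   `sites_lost`, `origin`.
#' @export
preselect <- function(candidates) {
  if (!length(candidates)) stop("no candidate sequences to rank", call. = FALSE)
  df <- data.frame(
    bases = vapply(candidates, `[[`, "", "bases"),
    residues = vapply(candidates, `[[`, "", "residues"),
    n_changes = vapply(candidates, `[[`, 1L, "n_changes"),
    changed = vapply(candidates, function(x)
      paste(x$changed_positions, collapse = ","), ""),
    gc = round(vapply(candidates, `[[`, 1, "gc"), 2),
    sites_gained = vapply(candidates, function(x) fmt_sites(x$sites_gained), ""),
    sites_lost = vapply(candidates, function(x) fmt_sites(x$sites_lost), ""),
    origin = vapply(candidates, `[[`, "", "origin"),
    stringsAsFactors = FALSE)
  ord <- order(df$n_changes, abs(df$gc - 50), df$bases)
  df <- df[ord, , drop = FALSE]
  df <- cbind(candidate = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}
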