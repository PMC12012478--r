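#' RNA secondary structure (sequence + dot-bracket)
#'
#' @param sequence RNA sequence (AUGC).
#' @param dot_bracket matching dot-bracket string (balanced, no
#'   pseudoknots).
#' @param name structure name.
#' @param numbering_offset number of the first residue (e.g. 52 for a
#'   3'UTR fragment starting at residue 52).
#' @return object of class \code{secondary_structure} with a \code{pairs}
#'   matrix (i, j, 1-based within the fragment).
#' @export
secondary_structure <- function(sequence, dot_bracket, name = "structure",
                                numbering_offset = 1) {
  sequence <- toupper(gsub("T", "U", sequence))
  if (nchar(sequence) != nchar(dot_bracket)) {
    stop("sequence and dot_bracket lengths differ")
  }
  if (grepl("[^AUGC]", sequence)) stop("sequence must contain only AUGC")
  chars <- strsplit(dot_bracket, "")[[1]]
  if (any(!chars %in% c("(", ")", "."))) {
    stop("dot_bracket may contain only '(', ')' and '.' ",
         "(pseudoknot notations are unsupported)")
  }
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced brackets at position ", i)
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced brackets: ", length(stack),
                          " unmatched '('")
  colnames(pairs) <- c("i", "j")
  structure(list(name = name, sequence = sequence,
                 dot_bracket = dot_bracket,
                 numbering_offset = numbering_offset,
                 pairs = pairs[order(pairs[, 1]), , drop = FALSE]),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf(">%s offset=%d (%d nt, %d base pairs)\n%s\n%s\n",
              x$name, x$numbering_offset, nchar(x$sequence),
              nrow(x$pairs), x$sequence, x$dot_bracket))
  invisible(x)
}

#' Transition-count graph from a dwell table
#'
#' Counts consecutive state pairs (no self-edges by construction of the
#' dwell table).
#'
#' @param dwells a \code{dwell_table}.
#' @param n_states number of states (defaults to the maximum index seen).
#' @return integer matrix of a -> b transition counts.
#' @export
build_transition_graph <- function(dwells, n_states = max(dwells$state)) {
  if (length(unique(dwells$state)) < 2) stop("need at least 2 states")
  K <- n_states
  g <- matrix(0L, K, K)
  s <- dwells$state
  for (i in seq_len(nrow(dwells) - 1)) {
    g[s[i], s[i + 1]] <- g[s[i], s[i + 1]] + 1L
  }
  g
}

#' Classify states as on- or off-pathway
#'
#' A state whose observed transitions (both directions pooled, counted
#' above \code{min_count}) connect it to exactly one partner state, and
#' which is neither the most folded nor the most unfolded terminus, is an
#' off-pathway (misfolded) dead end: it can only be entered from and left
#' into that single neighbor and never exchanges directly with the rest of
#' the network.
#'
#' @param graph transition-count matrix from [build_transition_graph()].
#' @param min_count minimum pooled count for an edge to be trusted.
#' @param terminals indices of the folded and unfolded termini (default:
#'   first and last state in level order).
#' @return data.frame with \code{state}, \code{classification},
#'   \code{n_partners} and \code{near_miss_partners} (partners with
#'   nonzero counts below \code{min_count}, reported for sensitivity).
#' @export
classify_off_pathway <- function(graph, min_count = 3,
                                 terminals = c(1, nrow(graph))) {
  K <- nrow(graph)
  pooled <- graph + t(graph)
  adj <- pooled >= min_count
  # connectivity check on the trusted edge set
  comp <- rep(NA_integer_, K)
  cid <- 0
  for (s in seq_len(K)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  if (cid > 1) {
    stop("transition graph is disconnected at min_count = ", min_count,
         "; components: ",
         paste(vapply(seq_len(cid), function(c_) {
           paste(which(comp == c_), collapse = ",")
         }, character(1)), collapse = " | "))
  }
  out <- data.frame(state = seq_len(K),
                    classification = "on_pathway",
                    n_partners = rowSums(adj),
                    stringsAsFactors = FALSE)
  out$near_miss_partners <- vapply(seq_len(K), function(s) {
    nm <- which(pooled[s, ] > 0 & pooled[s, ] < min_count)
    paste(nm, collapse = ",")
  }, character(1))
  pendant <- out$n_partners == 1 & !(out$state %in% terminals)
  out$classification[pendant] <- "off_pathway"
  out
}

# Decompose a single-hairpin structure into helices, outside-in. Each
# helix is a run of nested pairs; the unpaired nucleotides between a helix
# and the next helix inward (interior bulge/loop) are attributed to the
# unfolding step that opens the outer helix.
decompose_helices <- function(struct) {
  p <- struct$pairs
  if (!nrow(p)) stop("structure has no base pairs")
  # single hairpin: pair i-coordinates strictly increasing while j strictly
  # decreasing along the nesting order
  p <- p[order(p[, "i"]), , drop = FALSE]
  if (any(diff(p[, "j"]) >= 0)) {
    stop("multi-branched structures are unsupported: expected one hairpin")
  }
  helix_id <- cumsum(c(1, (diff(p[, "i"]) != 1) | (diff(p[, "j"]) != -1)))
  split.data.frame(as.data.frame(p), helix_id)
}

#' Enumerate sequential-unzipping intermediates of a hairpin
#'
#' Orders the base pairs along the force-propagation coordinate (the
#' terminal, closing helix opens first) and enumerates the intermediates
#' reached at every helix boundary. Each unfolding step disrupts one stem
#' region along with the adjacent interior bulge/loop nucleotides inward
#' of it; the final step releases the terminal loop, so the last
#' intermediate frees the whole fragment. Expected contour-length gains
#' follow the package's elastic conventions (ssRNA contour per released
#' nucleotide; the rigid stem offset is recovered only when the final
#' helix opens).
#'
#' @param struct a [secondary_structure()] (single hairpin).
#' @param model an [elastic_model()].
#' @return data.frame with one row per intermediate: \code{intermediate}
#'   (1 = first unzipping step), \code{helices_opened},
#'   \code{n_unfolded_nt} (cumulative released nucleotides),
#'   \code{expected_delta_contour} (nm from the fully folded state) and
#'   \code{fully_open} flag.
#' @export
enumerate_unzipping_intermediates <- function(struct, model) {
  hel <- decompose_helices(struct)
  n_total <- nchar(struct$sequence)
  n_hel <- length(hel)
  # nucleotides released by opening helix h: its own pairs (both strands)
  # plus unpaired nts between it and the next helix inward (both sides);
  # the innermost helix also releases the terminal loop
  released <- numeric(n_hel)
  for (h in seq_len(n_hel)) {
    cur <- hel[[h]]
    own <- 2 * nrow(cur)
    inner_gap <- if (h < n_hel) {
      nxt <- hel[[h + 1]]
      (min(nxt$i) - max(cur$i) - 1) + (min(cur$j) - max(nxt$j) - 1)
    } else {
      min(cur$j) - max(cur$i) - 1   # terminal loop
    }
    released[h] <- own + inner_gap
  }
  # nucleotides dangling outside the outermost helix are not part of the
  # folded unit; count them as released from the start (they carry tension)
  outer <- hel[[1]]
  pre <- min(outer$i) - 1 + (n_total - max(outer$j))
  cum_nt <- pre + cumsum(released)
  fully <- seq_len(n_hel) == n_hel
  dl <- cum_nt * model$ss_contour_per_nt - ifelse(fully, 1, 0) *
    model$folded_offset
  data.frame(intermediate = seq_len(n_hel),
             helices_opened = seq_len(n_hel),
             n_unfolded_nt = cum_nt,
             expected_delta_contour = dl,
             fully_open = fully)
}

#' Match observed contour-length gains to enumerated intermediates
#'
#' Maps each observed gain to the nearest enumerated intermediate within
#' \code{tolerance}; observations with two candidates within tolerance are
#' flagged ambiguous, and unmatched observations are reported as misfold
#' candidates (states whose length gain fits no sequential-unzipping
#' intermediate).
#'
#' @param observed observed contour-length gains from the fully folded
#'   state, nm.
#' @param enumerated data.frame from [enumerate_unzipping_intermediates()]
#'   (or any table with an \code{expected_delta_contour} column).
#' @param tolerance matching tolerance, nm (about 2-3 nt).
#' @return data.frame with one row per observation: \code{observed},
#'   \code{matched_intermediate} (NA if unmatched), \code{expected},
#'   \code{residual}, \code{ambiguous}, \code{misfold_candidate}.
#' @export
match_intermediates <- function(observed, enumerated, tolerance = 1.5) {
  if (!length(observed) || !nrow(enumerated)) {
    stop("both observed and enumerated lists must be non-empty")
  }
  exp_dl <- enumerated$expected_delta_contour
  out <- do.call(rbind, lapply(observed, function(o) {
    d <- abs(exp_dl - o)
    within <- which(d <= tolerance)
    best <- which.min(d)
    data.frame(observed = o,
               matched_intermediate =
                 if (length(within)) enumerated$intermediate[best]
                 else NA_integer_,
               expected = if (length(within)) exp_dl[best] else NA_real_,
               residual = if (length(within)) o - exp_dl[best]
                 else NA_real_,
               ambiguous = length(within) > 1,
               misfold_candidate = length(within) == 0)
  }))
  rownames(out) <- NULL
  out
}

#' Compare candidate structures by how well they explain observed gains
#'
#' Runs [match_intermediates()] against each candidate's intermediate set
#' and ranks the candidates by the sum of absolute residuals (unmatched
#' observations contribute the tolerance as penalty).
#'
#' @param observed observed contour-length gains, nm.
#' @param structures named list of [secondary_structure()] objects.
#' @param model an [elastic_model()].
#' @param tolerance matching tolerance, nm.
#' @return data.frame with \code{structure}, \code{total_abs_residual},
#'   \code{n_matched}; best structure first.
#' @export
compare_structures <- function(observed, structures, model,
                               tolerance = 1.5) {
  res <- do.call(rbind, lapply(names(structures), function(nm) {
    enum <- enumerate_unzipping_intermediates(structures[[nm]], model)
    m <- match_intermediates(observed, enum, tolerance)
    data.frame(structure = nm,
               total_abs_residual = sum(abs(m$residual), na.rm = TRUE) +
                 tolerance * sum(m$misfold_candidate),
               n_matched = sum(!m$misfold_candidate))
  }))
  res[order(res$total_abs_residual), ]
}
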