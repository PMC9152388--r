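#' Strict entity-level evaluation
#'
#' A predicted mention counts as correct iff its `(start, end, type)` triple
#' exactly equals a gold mention in the same sentence (strict match, the
#' usual convention for clinical NER shared tasks). Micro-averaged precision
#' is correct/predicted, recall correct/gold, and `F1 = 2PR/(P+R)` (0 when
#' `P + R = 0`; an empty prediction set has precision 0 by convention).
#' Duplicate predicted mentions are deduplicated before matching. Predicted
#' mentions that miss are further classified for error analysis: a prediction
#' that overlaps a gold span of the same type but differs in extent is a
#' *boundary error*; one whose span equals a gold span but whose type differs
#' is a *type error*; anything else is spurious.
#'
#' @param gold,pred Sentence-aligned lists. Each element is either a
#'   [labeled_sentence()]/prediction list with a `mentions` field or a bare
#'   [entity_mentions()] data frame.
#' @param schema A [tag_schema()].
#' @return An object of class `eval_result` with `overall` (micro-averaged
#'   counts and percentage P/R/F1), `per_type` (one row per type), `errors`
#'   (boundary / type / spurious / missed tallies per type), and `macro`
#'   (unweighted mean P/R/F1 over the types present in the gold standard).
#' @export
strict_match_eval <- function(gold, pred, schema = tag_schema()) {
  if (length(gold) != length(pred)) {
    stop("gold and pred must be sentence-aligned (", length(gold), " vs ",
         length(pred), " sentences)")
  }
  get_m <- function(x) {
    m <- if (is.data.frame(x)) x else x$mentions
    unique(m[, c("start", "end", "type")])
  }
  types <- schema$types
  zero <- stats::setNames(numeric(length(types)), types)
  n_gold <- zero; n_pred <- zero; n_corr <- zero
  boundary <- zero; type_err <- zero; spurious <- zero
  for (s in seq_along(gold)) {
    gm <- get_m(gold[[s]]); pm <- get_m(pred[[s]])
    gkey <- paste(gm$start, gm$end, gm$type)
    pkey <- paste(pm$start, pm$end, pm$type)
    for (ty in types) {
      n_gold[ty] <- n_gold[ty] + sum(gm$type == ty)
      n_pred[ty] <- n_pred[ty] + sum(pm$type == ty)
      n_corr[ty] <- n_corr[ty] + sum(pkey[pm$type == ty] %in% gkey)
    }
    miss <- which(!(pkey %in% gkey))
    for (i in miss) {
      ty <- pm$type[i]
      same_span <- gm$start == pm$start[i] & gm$end == pm$end[i]
      overlap_same_type <- gm$type == ty & gm$start < pm$end[i] &
        gm$end > pm$start[i]
      if (any(same_span)) {
        type_err[ty] <- type_err[ty] + 1
      } else if (any(overlap_same_type)) {
        boundary[ty] <- boundary[ty] + 1
      } else {
        spurious[ty] <- spurious[ty] + 1
      }
    }
  }
  prf <- function(corr, pred_n, gold_n) {
    corr <- unname(corr); pred_n <- unname(pred_n); gold_n <- unname(gold_n)
    p <- if (pred_n > 0) 100 * corr / pred_n else 0
    r <- if (gold_n > 0) 100 * corr / gold_n else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p, recall = r, f1 = f)
  }
  per_type <- do.call(rbind, lapply(types, function(ty) {
    m <- prf(n_corr[ty], n_pred[ty], n_gold[ty])
    data.frame(type = ty, gold = n_gold[ty], predicted = n_pred[ty],
               correct = n_corr[ty], precision = m["precision"],
               recall = m["recall"], f1 = m["f1"], row.names = NULL)
  }))
  ov <- prf(sum(n_corr), sum(n_pred), sum(n_gold))
  overall <- data.frame(gold = sum(n_gold), predicted = sum(n_pred),
                        correct = sum(n_corr), precision = ov["precision"],
                        recall = ov["recall"], f1 = ov["f1"],
                        row.names = NULL)
  errors <- data.frame(type = types, boundary = unname(boundary),
                       type_error = unname(type_err),
                       spurious = unname(spurious),
                       missed = unname(n_gold - n_corr), row.names = NULL)
  # macro average over the types present in the gold standard
  present <- per_type$gold > 0
  macro <- if (any(present)) {
    data.frame(precision = mean(per_type$precision[present]),
               recall = mean(per_type$recall[present]),
               f1 = mean(per_type$f1[present]))
  } else {
    data.frame(precision = 0, recall = 0, f1 = 0)
  }
  structure(list(overall = overall, per_type = per_type, errors = errors,
                 macro = macro),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("strict entity-level evaluation: P %.2f%%  R %.2f%%  F1 %.2f%%\n",
              x$overall$precision, x$overall$recall, x$overall$f1))
  cat(sprintf("  (gold %d, predicted %d, correct %d)\n", x$overall$gold,
              x$overall$predicted, x$overall$correct))
  invisible(x)
}

#' Per-type report of an evaluation
#'
#' One row per entity type with counts, percentage P/R/F1 (2 decimals) and
#' the boundary-error / type-error tallies from the error taxonomy.
#'
#' @param result An `eval_result` from [strict_match_eval()].
#' @return Data frame keyed by type code.
#' @export
per_type_report <- function(result) {
  df <- merge(result$per_type, result$errors, by = "type", sort = FALSE)
  df$precision <- round(df$precision, 2)
  df$recall <- round(df$recall, 2)
  df$f1 <- round(df$f1, 2)
  df
}
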