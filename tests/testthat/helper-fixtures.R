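# Shared fixtures built in code; nothing on disk.

cal100 <- calibrateScale(1000, 100)   # 100 um per pixel

# a VeinSectionSet of horizontal sections at given rows (one per section),
# with npos positions each, for QC unit tests
mkSectionSet <- function(rows, npos = 5, c1 = 20, c2 = 120) {
  segs <- lapply(rows, function(r) c(r, c1, r, c2))
  myxometry:::buildSectionSet(segs, spacing = (c2 - c1) / (npos - 1),
                              min_positions = npos)
}

# a widths table assigning one width per position, recycled per section
mkWidths <- function(vss, widths_by_section) {
  p <- positions(vss)
  ids <- unique(p$section_id)
  do.call(rbind, lapply(seq_along(ids), function(i) {
    pi <- p[p$section_id == ids[i], ]
    w <- rep_len(widths_by_section[[i]], nrow(pi))
    data.frame(section_id = pi$section_id, pos_index = pi$pos_index,
               width_um = w)
  }))
}

statusOf <- function(vss, id) {
  s <- sections(vss)
  s$status[s$section_id == id]
}

reasonOf <- function(vss, id) {
  s <- sections(vss)
  s$reject_reason[s$section_id == id]
}
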