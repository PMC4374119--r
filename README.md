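# wikichem

Chemical-structure harvesting, curation and search for wiki-markup
infobox corpora.

Wikipedia describes well over ten thousand chemicals through two markup
templates — `{{Chembox}}` for general chemicals and `{{Infobox drug}}`
(Drugbox) for pharmaceuticals — whose parameters include SMILES strings
entered by volunteers. That crowd-sourced corpus is valuable and noisy in
equal measure: a sizable minority of pages carry no SMILES, hundreds of
strings violate the SMILES grammar (dominated by pyrrole-type aromatic
nitrogen written `n` instead of `[nH]`), pages duplicate each other under
synonyms, and infobox structures disagree with external databases.
`wikichem` re-implements the back end of a structure explorer for such a
corpus as an R package plus CLI:

* **Harvest** — balanced-brace template parsing that collects every
  `SMILES`/`SMILES1`/... parameter, including nested Chembox section
  sub-templates; pages without SMILES are tallied, malformed markup is
  flagged, never fatal.
* **Validate** — a SMILES parser with a classified error taxonomy
  (`PYRROLE_NITROGEN`, `UNCLOSED_RING`, `UNCLOSED_PARENTHESIS`,
  `BARE_ATOM_NEEDS_BRACKETS`, `KEKULIZATION_FAILURE`, `BAD_TOKEN`,
  `VALENCE_ERROR`), each with a character position and — for the
  pyrrole-nitrogen case — a repaired SMILES that is guaranteed to parse.
  Kekulization is solved as a perfect matching on the subgraph of aromatic
  atoms that require a double bond.
* **Canonicalize** — Morgan-style iterative refinement with deterministic
  tie-breaking yields a stereo-aware canonical SMILES (plus a
  stereo-stripped variant), used for exact search, within-page
  consolidation and cross-page duplicate detection.
* **Index & search** — every record carries a 512-bit fragment-dictionary
  fingerprint serialized as 16 unsigned 32-bit words inside a JSON index
  file, alongside canonical structure, Hill formula, molecular weight and
  page title. Three search modes:
  * *exact*: canonical-string equality;
  * *substructure*: two-step search — fingerprint pre-screen
    (`query bits ⊆ record bits`, sound because every substructure of the
    query is a substructure of any superstructure of the query) followed by
    VF2-style subgraph-isomorphism confirmation in C++;
  * *similarity*: Tanimoto score `T(A,B) = |A∧B| / |A∨B|` over the
    fingerprints.
  Substructure hits are ranked by ascending `|ΔMW|` from the query,
  similarity hits by descending score with `|ΔMW|` tie-breaks, and the
  exact match is always forced to the top — so a query that is itself in
  the index is always hit number one.
* **Curate** — cross-page duplicate groups (stereo-aware and
  stereo-stripped), Wikipedia-vs-reference disagreement classification
  (match / same formula, different structure / formula mismatch), and
  Murcko scaffold frequency tables (the data behind molecule-cloud style
  diversity figures).
* **Synthesize** — a seeded generator of random valid molecules and
  synthetic wiki pages exhibiting every behavior above, with a ground-truth
  manifest, so the whole pipeline is testable offline.

## Worked example

```r
library(wikichem)

# the classic mis-encoding: benzimidazole written with a bare aromatic n
issue <- parse_smiles("n2c1ccccc1nc2")
#> <parse_issue PYRROLE_NITROGEN at 0: pyrrole-type nitrogen written as
#>  bare 'n'; must be [nH] [fix: [nH]2c1ccccc1nc2]>
fixed <- parse_smiles(issue$suggested_fix)
molecular_formula(fixed)                      # "C7H6N2"
molecular_weight(fixed)                       # 118.14
canonical_smiles(fixed)$canonical_smiles      # "c1nc2ccccc2[nH]1"

# synthetic corpus -> extract -> consolidate -> index -> search
corpus  <- synth_wiki_corpus(gen_config(seed = 42, n_molecules = 50))
entries <- do.call(rbind, lapply(corpus$pages, extract_entries))
cons    <- consolidate(entries)
# 49 SMILES parameters -> 45 kept + 1 error + 3 within-page duplicates
idx <- build_index(data.frame(smiles = cons$kept$smiles_raw,
                              page   = cons$kept$page))
#> <chem_index: 45 records, dictionary wikichem-fragfp-v1, ...; 0 errors>

search_substructure("c1ccccc1", idx)
#> <search_result substructure: 3 hits>
#>        structure     mf     mw                    page score mw_delta
#> 1      Cc1ccccc1   C7H8  92.14 Synthetic compound 0014    NA    14.03
#> 2 CCc1ccc(C)cc1F C9H11F 138.18 Synthetic compound 0039    NA    60.07
#> 3 Brc1ccc(C)cc1C C8H9Br 185.06 Synthetic compound 0045    NA   106.95

top_scaffolds(idx, n = 5)
#> <scaffold_report: 5 scaffolds, 10 records covered>
#>   scaffold_smiles count
#> 1           C1CC1     3
#> 2        c1ccccc1     3
#> 3        c1ccncc1     2
#> ...
```

The three substructure hits are exactly the benzene-containing records of
the index (screen + confirm equals brute-force graph matching), ordered by
molecular-weight distance from benzene.

## Command line

```sh
wikichem="Rscript inst/cli/wikichem"   # or install the launcher on PATH
$wikichem synth --seed 42 --pages 200 -o corpus.jsonl --manifest manifest.json
$wikichem extract corpus.jsonl -o index.json --errors errors.tsv
$wikichem search --mode sub --query 'c1ccccc1' --index index.json
$wikichem search --mode sim --query 'CCO' --index index.json --top 10
$wikichem dedupe index.json
$wikichem scaffolds index.json --top 250 --format tsv
$wikichem export-smiles index.json -o smiles.txt
$wikichem validate smiles.txt        # exit 2 when errors are found
```

Exit codes: 0 success, 1 usage error, 2 data errors found (`validate`),
3 I/O failure.

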