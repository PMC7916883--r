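# Crystal-structure accessions

The structure-derived checks in the test suite and the worked examples in
the package documentation operate on the two serine
hydroxymethyltransferase crystal structures, PDB entries **1DFO**
(mesophilic, *E. coli*) and **4P3M** (psychrophilic, *P. ingrahamii*).
These files are not redistributed with the package. To enable the
structure-derived checks, download them from the Protein Data Bank
(<https://www.rcsb.org>) and place them here before installing:

    inst/extdata/accessions/1DFO.pdb
    inst/extdata/accessions/4P3M.pdb

Without the files, the corresponding tests report a single clear failure
and everything else (all synthetic-data checks) runs unaffected.
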