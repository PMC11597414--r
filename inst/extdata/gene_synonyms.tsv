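# Editable gene-name synonym table: raw (cleaned, upper-case, spaces and
# underscores removed) -> canonical symbol. Extends the built-in mapping.
raw	symbol
CYTOCHROMEOXIDASESUBUNIT1	cox1
CYTOCHROMEOXIDASESUBUNIT2	cox2
CYTOCHROMEOXIDASESUBUNIT3	cox3
CYTOCHROMECOXIDASESUBUNITI	cox1
CYTOCHROMECOXIDASESUBUNITII	cox2
CYTOCHROMECOXIDASESUBUNITIII	cox3
NADHDEHYDROGENASESUBUNIT1	nad1
NADHDEHYDROGENASESUBUNIT2	nad2
NADHDEHYDROGENASESUBUNIT3	nad3
NADHDEHYDROGENASESUBUNIT4	nad4
NADHDEHYDROGENASESUBUNIT4L	nad4l
NADHDEHYDROGENASESUBUNIT5	nad5
NADHDEHYDROGENASESUBUNIT6	nad6
ATPSYNTHASEF0SUBUNIT6	atp6
ATPSYNTHASEF0SUBUNIT8	atp8
SMALLSUBUNITRIBOSOMALRNA	rrnS
LARGESUBUNITRIBOSOMALRNA	rrnL
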