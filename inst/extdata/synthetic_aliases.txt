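MIMAT0000433	hsa-miR-142-3p;hsa-miR-142-3p.1;hsa-miR-142-3p;
MIMAT0000062	hsa-let-7a;hsa-let-7a-5p;
MI0000060	hsa-let-7a-1;
SMIMAT0099	syn-miR-old;syn-miR-new;
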