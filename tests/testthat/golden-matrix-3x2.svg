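<?xml version="1.0" encoding="UTF-8"?>
<svg xmlns="http://www.w3.org/2000/svg" width="208" height="193" font-family="Helvetica" font-size="11">
<rect width="100%" height="100%" fill="#FFFFFF"/>
<text x="128.48" y="19.00" text-anchor="middle">GENE1(A1B)</text>
<text x="174.48" y="19.00" text-anchor="middle">GENE2(C2D)</text>
<text x="99.48" y="43.85" text-anchor="end">Lung carcinoma</text>
<g id="tumor-lung_carcinoma-GENE1_A1B_">
<rect x="105.48" y="25.00" width="46.00" height="30.00" fill="#FFFFFF" stroke="#CCCCCC" stroke-width="1"/>
<line x1="110.48" y1="40.00" x2="146.48" y2="40.00" stroke="#555555" stroke-width="2"/>
</g>
<g id="tumor-lung_carcinoma-GENE2_C2D_">
<rect x="151.48" y="25.00" width="46.00" height="30.00" fill="#FFFFFF" stroke="#CCCCCC" stroke-width="1"/>
</g>
<text x="99.48" y="73.85" text-anchor="end">Melanoma</text>
<g id="tumor-melanoma-GENE1_A1B_">
<rect x="105.48" y="55.00" width="46.00" height="30.00" fill="#FFFFFF" stroke="#CCCCCC" stroke-width="1"/>
<line x1="110.48" y1="70.00" x2="146.48" y2="70.00" stroke="#555555" stroke-width="2"/>
</g>
<g id="tumor-melanoma-GENE2_C2D_">
<rect x="151.48" y="55.00" width="46.00" height="30.00" fill="#FFFFFF" stroke="#CCCCCC" stroke-width="1"/>
</g>
<text x="99.48" y="111.85" text-anchor="end">Drug One</text>
<g id="cell-drug_one-GENE1_A1B_" data-state="consistent">
<rect x="105.48" y="93.00" width="46.00" height="30.00" fill="#FFFFFF" stroke="#CCCCCC" stroke-width="1"/>
<rect x="114.68" y="96.00" width="27.60" height="24.00" fill="#2E8B57"/>
<rect x="114.68" y="109.20" width="27.60" height="10.80" fill="#000000"/>
</g>
<g id="cell-drug_one-GENE2_C2D_" data-state="missing">
<rect x="151.48" y="93.00" width="46.00" height="30.00" fill="#FFFFFF" stroke="#CCCCCC" stroke-width="1"/>
</g>
<text x="99.48" y="141.85" text-anchor="end">Drug Three</text>
<g id="cell-drug_three-GENE1_A1B_" data-state="dtc_only">
<rect x="105.48" y="123.00" width="46.00" height="30.00" fill="#FFFFFF" stroke="#CCCCCC" stroke-width="1"/>
<line x1="109.48" y1="149.00" x2="147.48" y2="127.00" stroke="#000000" stroke-width="2"/>
</g>
<g id="cell-drug_three-GENE2_C2D_" data-state="cgi_only">
<rect x="151.48" y="123.00" width="46.00" height="30.00" fill="#FFFFFF" stroke="#CCCCCC" stroke-width="1"/>
<rect x="160.68" y="145.20" width="27.60" height="4.80" fill="#D5E8DD"/>
</g>
<text x="99.48" y="171.85" text-anchor="end">Drug Two</text>
<g id="cell-drug_two-GENE1_A1B_" data-state="conflicting">
<rect x="105.48" y="153.00" width="46.00" height="30.00" fill="#FFFFFF" stroke="#CCCCCC" stroke-width="1"/>
<rect x="114.68" y="160.80" width="27.60" height="19.20" fill="#CD6155"/>
<rect x="120.20" y="169.20" width="16.56" height="10.80" fill="#000000"/>
</g>
<g id="cell-drug_two-GENE2_C2D_" data-state="missing">
<rect x="151.48" y="153.00" width="46.00" height="30.00" fill="#FFFFFF" stroke="#CCCCCC" stroke-width="1"/>
</g>
</svg>
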