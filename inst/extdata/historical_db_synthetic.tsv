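name	year	description
Great River Inundation	1954	the great river rose over its banks and water covered whole towns
Northern Railway Opening	1935	the first northern railway line opened and trains reached the county
Coastal Reconstruction Drive	1962	coastal districts were rebuilt street by street after the storms
National Grain Campaign	1958	the national grain campaign sent brigades to every commune
Southern Bridge Completion	1968	the southern bridge was completed and the ferry crossings ended
City Electrification Push	1972	electric light arrived in the city lanes during the big push
Provincial Harvest Festival	1984	the provincial harvest festival filled the squares with drums
Eastern Harbor Expansion	1990	the eastern harbor was expanded and foreign ships began to call
Mountain Road Project	1978	the mountain road project connected the high villages at last
New Calendar Reform	1949	the new calendar reform changed how every household counted days
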